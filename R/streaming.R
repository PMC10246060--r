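# OpenIGTLink-subset wire codec and the real-time loop: coil-pose TRANSFORM
# in -> dA/dt -> surrogate prediction -> magnitude IMAGE out.
#
# Wire layout (big-endian throughout, header 58 bytes):
#   uint16 version | char[12] type_name (null-padded) | char[20] device_name |
#   uint32 ts_sec | uint32 ts_nsec | uint64 body_size | uint64 crc64(body)
# TRANSFORM body: 12 float32 (3x3 rotation column-major, then offset) = 48 B.
# IMAGE body: uint32 dims[3] | float32 spacing[3] | uint8 dtype (2 = float64)
# followed by the raw voxels, column-major. Voxels travel as float64 so the
# streamed field is bit-identical to the in-process prediction.

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "big")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "big")
.u64 <- function(x) c(.u32(x %/% 2^32), .u32(x %% 2^32))
.f32 <- function(x) writeBin(as.numeric(x), raw(), size = 4, endian = "big")
.f64 <- function(x) writeBin(as.numeric(x), raw(), size = 8, endian = "big")
.chr_pad <- function(s, n) {
  b <- charToRaw(s)
  c(b, raw(n - length(b)))
}
.rd_u16 <- function(b) readBin(b, integer(), size = 2, endian = "big", signed = FALSE)
.rd_u32 <- function(b) {
  v <- readBin(b, integer(), size = 4, endian = "big")
  if (v < 0) v + 2^32 else as.numeric(v)
}
.rd_f32 <- function(b, n = 1L) readBin(b, numeric(), n = n, size = 4, endian = "big")

IGT_HEADER_BYTES <- 58L

#' Encode an OpenIGTLink-subset message
#'
#' @param kind "TRANSFORM" (payload a [RigidTransform]) or "IMAGE" (payload a
#'   scalar [VolumeGrid]).
#' @param payload the payload object.
#' @param device_name device string, at most 20 ASCII characters.
#' @param timestamp length-2 numeric (seconds, nanoseconds); defaults to the
#'   current wall clock.
#' @return raw vector: 58-byte header followed by the body.
#' @export
encodeMessage <- function(kind = c("TRANSFORM", "IMAGE"), payload,
                          device_name = "tmsfield", timestamp = NULL) {
  kind <- match.arg(kind)
  if (nchar(device_name) > 20L) stop("device_name exceeds 20 characters")
  if (is.null(timestamp)) {
    now <- as.numeric(Sys.time())
    timestamp <- c(floor(now), round((now - floor(now)) * 1e9))
  }
  body <- switch(kind,
    TRANSFORM = {
      m <- transformMatrix(.as_rigid(payload))
      .f32(c(m[1:3, 1], m[1:3, 2], m[1:3, 3], m[1:3, 4]))
    },
    IMAGE = {
      if (!is(payload, "VolumeGrid") || nComponents(payload) != 1L)
        stop("IMAGE payload must be a scalar VolumeGrid")
      d <- gridShape(payload)
      sp <- .grid_spacing(gridAffine(payload))
      c(.u32(d[1]), .u32(d[2]), .u32(d[3]), .f32(sp), as.raw(2L),
        .f64(as.numeric(gridValues(payload))))
    })
  c(.u16(2L), .chr_pad(kind, 12L), .chr_pad(device_name, 20L),
    .u32(timestamp[1]), .u32(timestamp[2]), .u64(length(body)),
    cpp_crc64(body), body)
}

#' Decode an OpenIGTLink-subset message
#'
#' Verifies framing, the supported type set and the body CRC.
#'
#' @param bytes raw vector holding exactly one message.
#' @return an [IGTMessage].
#' @export
decodeMessage <- function(bytes) {
  if (length(bytes) < IGT_HEADER_BYTES)
    stop("framing error: fewer than 58 header bytes")
  version <- .rd_u16(bytes[1:2])
  type_name <- rawToChar(bytes[3:14][bytes[3:14] != as.raw(0)])
  device_name <- rawToChar(bytes[15:34][bytes[15:34] != as.raw(0)])
  ts_sec <- .rd_u32(bytes[35:38])
  ts_nsec <- .rd_u32(bytes[39:42])
  body_size <- .rd_u32(bytes[43:46]) * 2^32 + .rd_u32(bytes[47:50])
  crc <- bytes[51:58]
  if (!type_name %in% c("TRANSFORM", "IMAGE"))
    stop(sprintf("unsupported message type '%s'", type_name))
  if (length(bytes) < IGT_HEADER_BYTES + body_size)
    stop("framing error: truncated body")
  body <- bytes[IGT_HEADER_BYTES + seq_len(body_size)]
  if (!identical(cpp_crc64(body), crc))
    stop("integrity error: body CRC mismatch")
  new("IGTMessage", version = as.integer(version), type_name = type_name,
      device_name = device_name, ts_sec = ts_sec, ts_nsec = ts_nsec,
      body = body)
}

#' Split a byte stream into messages
#'
#' Uses each header's body_size for framing.
#'
#' @param bytes raw vector holding zero or more concatenated messages.
#' @return list of [IGTMessage].
#' @export
decodeMessageStream <- function(bytes) {
  out <- list()
  while (length(bytes) > 0) {
    if (length(bytes) < IGT_HEADER_BYTES) stop("framing error: trailing bytes")
    body_size <- .rd_u32(bytes[43:46]) * 2^32 + .rd_u32(bytes[47:50])
    n <- IGT_HEADER_BYTES + body_size
    if (length(bytes) < n) stop("framing error: truncated body")
    out[[length(out) + 1L]] <- decodeMessage(bytes[seq_len(n)])
    bytes <- bytes[-seq_len(n)]
  }
  out
}

#' Extract payloads from decoded messages
#'
#' `messageTransform` rebuilds the [RigidTransform] of a TRANSFORM message;
#' `messageImage` the scalar [VolumeGrid] of an IMAGE message (axis-aligned
#' affine from the carried spacings; the origin is session context and is not
#' on the wire).
#'
#' @param msg an [IGTMessage].
#' @return see descriptions.
#' @export
messageTransform <- function(msg) {
  if (msg@type_name != "TRANSFORM") stop("not a TRANSFORM message")
  v <- .rd_f32(msg@body, 12L)
  m <- diag(4)
  m[1:3, 1] <- v[1:3]; m[1:3, 2] <- v[4:6]; m[1:3, 3] <- v[7:9]
  m[1:3, 4] <- v[10:12]
  # float32 quantization perturbs orthonormality; re-orthonormalize via SVD
  R <- m[1:3, 1:3]
  sv <- svd(R)
  m[1:3, 1:3] <- sv$u %*% t(sv$v)
  rigidTransform(m)
}

#' @rdname messageTransform
#' @export
messageImage <- function(msg) {
  if (msg@type_name != "IMAGE") stop("not an IMAGE message")
  d <- c(.rd_u32(msg@body[1:4]), .rd_u32(msg@body[5:8]), .rd_u32(msg@body[9:12]))
  sp <- .rd_f32(msg@body[13:24], 3L)
  dtype <- as.integer(msg@body[25])
  if (dtype != 2L) stop("unsupported IMAGE dtype")
  vals <- readBin(msg@body[-(1:25)], numeric(), n = prod(d), size = 8,
                  endian = "big")
  volumeGrid(array(vals, c(d, 1L)), diag(c(sp, 1)))
}

# ---------------------------------------------------------------------------
# Transports
# ---------------------------------------------------------------------------

#' In-process transport (a pair of ordered byte-frame queues)
#'
#' Returns two endpoints, `client` and `server`, each with `send(bytes)` and
#' `recv()` closures. `recv()` returns NULL when no frame is pending.
#' Delivery is ordered and reliable, matching the transport contract of the
#' streaming loop; a TCP transport deployable against navigation software can
#' implement the same interface.
#'
#' @return list with elements `client` and `server`.
#' @export
localTransport <- function() {
  q_cs <- new.env(parent = emptyenv())  # client -> server
  q_sc <- new.env(parent = emptyenv())  # server -> client
  q_cs$frames <- list(); q_sc$frames <- list()
  endpoint <- function(outq, inq) {
    list(
      send = function(bytes) {
        outq$frames[[length(outq$frames) + 1L]] <- bytes
        invisible(TRUE)
      },
      recv = function() {
        if (!length(inq$frames)) return(NULL)
        f <- inq$frames[[1L]]
        inq$frames[[1L]] <- NULL
        f
      })
  }
  list(client = endpoint(q_cs, q_sc), server = endpoint(q_sc, q_cs))
}

#' TCP transport endpoint
#'
#' Same `send`/`recv` interface as [localTransport()], framed by the message
#' headers themselves (58 bytes + body_size). Blocking; intended for
#' deployment against OpenIGTLink-speaking navigation software.
#'
#' @param host host name (clients) .
#' @param port TCP port.
#' @param server open as listening endpoint.
#' @return list with `send`, `recv`, `close`.
#' @export
tcpTransport <- function(host = "localhost", port = 18944L, server = FALSE) {
  con <- socketConnection(host = host, port = port, server = server,
                          blocking = TRUE, open = "a+b")
  list(
    send = function(bytes) {
      writeBin(bytes, con)
      flush(con)
      invisible(TRUE)
    },
    recv = function() {
      hdr <- readBin(con, raw(), IGT_HEADER_BYTES)
      if (length(hdr) < IGT_HEADER_BYTES) return(NULL)
      body_size <- .rd_u32(hdr[43:46]) * 2^32 + .rd_u32(hdr[47:50])
      body <- if (body_size > 0) readBin(con, raw(), body_size) else raw(0)
      c(hdr, body)
    },
    close = function() close(con))
}

# ---------------------------------------------------------------------------
# Real-time loop
# ---------------------------------------------------------------------------

# reduced-FOV inputs for one pose: cropped conductivity + dA/dt on the FOV grid
.fov_inputs <- function(head, cv, coil, pose, fov_shape) {
  dims <- gridShape(cv)
  proj <- coilScalpProjection(head, pose)
  ctr <- round(worldToVoxel(gridAffine(cv), matrix(proj, 1)))[1, ]
  start <- as.integer(ctr - fov_shape %/% 2)
  sigma <- .crop_zerofill(gridValues(cv), start, fov_shape)
  fov_affine <- gridAffine(cv)
  fov_affine[1:3, 4] <- voxelToWorld(gridAffine(cv), matrix(start, 1))[1, ]
  fov_grid <- volumeGrid(array(0, c(fov_shape, 1L)), fov_affine)
  dadt <- dadtField(coil, pose, fov_grid)
  list(sigma = sigma, dadt = dadt, affine = fov_affine)
}

#' Run the streaming server loop
#'
#' For each received TRANSFORM (a coil pose) the server computes the coil
#' dA/dt over the reduced FOV at the pose's scalp projection, predicts the
#' E-field with the surrogate, and replies with the field-magnitude IMAGE.
#' Per run it records the prediction component (`cnn_seconds`: dA/dt +
#' network inference) and the visualization-side component (`vis_seconds`:
#' image encoding + send) separately. A malformed inbound frame triggers an
#' identity-TRANSFORM error reply from device "ERROR" and the loop continues;
#' an empty transport aborts the session with partial statistics (warning).
#'
#' @param model a [TrainedSurrogate].
#' @param head a [HeadGeometry].
#' @param cv a [ConductivityVolume].
#' @param coil a [CoilModel].
#' @param transport a transport endpoint (see [localTransport()]), server side.
#' @param n_runs number of runs to serve.
#' @param fov_shape the model's training FOV.
#' @return SessionStats: list with `runs` (data.frame run, cnn_seconds,
#'   vis_seconds), `n_runs`, `config`.
#' @export
runServerLoop <- function(model, head, cv, coil, transport, n_runs,
                          fov_shape = c(24L, 24L, 24L)) {
  recs <- vector("list", n_runs)
  done <- 0L
  while (done < n_runs) {
    raw_in <- transport$recv()
    if (is.null(raw_in)) {
      warning(sprintf("transport exhausted after %d/%d runs; returning partial stats", done, n_runs))
      break
    }
    msg <- tryCatch(decodeMessage(raw_in), error = function(e) e)
    if (inherits(msg, "error") ||
        !is(msg, "IGTMessage") || msg@type_name != "TRANSFORM") {
      transport$send(encodeMessage("TRANSFORM", rigidTransform(diag(4)),
                                   device_name = "ERROR"))
      next
    }
    pose <- messageTransform(msg)
    t0 <- as.numeric(Sys.time())
    fov <- .fov_inputs(head, cv, coil, pose, fov_shape)
    pred <- predictEfield(model, fov$sigma, gridValues(fov$dadt))
    mag <- volumeGrid(gridValues(pred$magnitude), fov$affine)
    t1 <- as.numeric(Sys.time())
    transport$send(encodeMessage("IMAGE", mag, device_name = "tmsfield"))
    t2 <- as.numeric(Sys.time())
    done <- done + 1L
    recs[[done]] <- c(cnn_seconds = t1 - t0, vis_seconds = t2 - t1)
  }
  runs <- as.data.frame(do.call(rbind, recs[seq_len(done)]))
  if (done > 0L) runs <- cbind(run = seq_len(done), runs)
  structure(list(runs = runs, n_runs = done,
                 config = list(fov_shape = fov_shape)),
            class = "SessionStats")
}

#' Drive a full in-process client/server session
#'
#' Sends one TRANSFORM per pose from the client side, runs the server loop,
#' and collects the IMAGE replies.
#'
#' @param model,head,cv,coil,fov_shape as in [runServerLoop()].
#' @param poses list of [RigidTransform] coil poses.
#' @return list with `stats` (SessionStats) and `images` (list of scalar
#'   [VolumeGrid]s in pose order).
#' @export
runSession <- function(model, head, cv, coil, poses,
                       fov_shape = c(24L, 24L, 24L)) {
  tr <- localTransport()
  for (p in poses)
    tr$client$send(encodeMessage("TRANSFORM", p, device_name = "navigation"))
  stats <- runServerLoop(model, head, cv, coil, tr$server, length(poses),
                         fov_shape)
  images <- list()
  repeat {
    f <- tr$client$recv()
    if (is.null(f)) break
    images[[length(images) + 1L]] <- messageImage(decodeMessage(f))
  }
  list(stats = stats, images = images)
}
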