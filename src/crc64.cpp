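#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// CRC-64/ECMA-182 (polynomial 0x42F0E1EBA9EA3693, init 0, MSB-first, no final
// xor) -- the checksum the OpenIGTLink wire format uses for message bodies.

static uint64_t crc64_table[256];
static bool crc64_ready = false;

static void crc64_init() {
  const uint64_t poly = 0x42F0E1EBA9EA3693ULL;
  for (int i = 0; i < 256; ++i) {
    uint64_t crc = (uint64_t)i << 56;
    for (int b = 0; b < 8; ++b)
      crc = (crc & 0x8000000000000000ULL) ? (crc << 1) ^ poly : (crc << 1);
    crc64_table[i] = crc;
  }
  crc64_ready = true;
}

// [[Rcpp::export]]
RawVector cpp_crc64(RawVector data) {
  if (!crc64_ready) crc64_init();
  uint64_t crc = 0;
  const int n = data.size();
  for (int i = 0; i < n; ++i)
    crc = (crc << 8) ^ crc64_table[(uint8_t)((crc >> 56) ^ data[i])];
  RawVector out(8);
  for (int i = 0; i < 8; ++i) out[i] = (uint8_t)(crc >> (8 * (7 - i)));  // big-endian
  return out;
}
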