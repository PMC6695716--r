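# CRC-32 (IEEE 802.3): reflected polynomial 0xEDB88320, init and final XOR
# 0xFFFFFFFF. Table-driven; values are held as R's 32-bit integers (logical
# shifts per bitwShiftR) and converted to an unsigned double at the end.

.crc_cache <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (!is.null(.crc_cache$table)) return(.crc_cache$table)
  poly <- -306674912L  # 0xEDB88320 as a signed 32-bit integer
  tbl <- integer(256)
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) {
        bitwXor(bitwShiftR(c, 1L), poly)
      } else {
        bitwShiftR(c, 1L)
      }
    }
    tbl[i + 1L] <- c
  }
  .crc_cache$table <- tbl
  tbl
}

#' CRC-32 checksum
#'
#' Standard CRC-32 as used to protect the transferred waveform payloads
#' (IEEE 802.3 polynomial, bit-reflected, initial value and final XOR
#' `0xFFFFFFFF`). The empty payload checksums to 0;
#' `crc32("123456789")` is the standard check value 3421780262.
#'
#' @param payload A raw vector, a single character string (taken as its
#'   bytes), or an integer vector of byte values 0-255.
#' @return Unsigned 32-bit checksum as a double.
#' @export
crc32 <- function(payload) {
  bytes <- if (is.raw(payload)) {
    as.integer(payload)
  } else if (is.character(payload)) {
    if (length(payload) != 1L) abort("character payload must be one string")
    as.integer(charToRaw(payload))
  } else {
    p <- as.integer(payload)
    if (length(p) > 0 && (any(p < 0L) || any(p > 255L))) {
      abort("integer payload must contain byte values 0-255")
    }
    p
  }
  tbl <- crc32_table()
  crc <- -1L  # 0xFFFFFFFF
  for (b in bytes) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   tbl[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  crc <- bitwXor(crc, -1L)
  u <- as.numeric(crc)
  if (u < 0) u + 2^32 else u
}

# big-endian byte serialization of 16-bit samples, for CRC verification
samples_to_bytes <- function(samples) {
  s <- as.integer(samples)
  if (length(s) == 0) return(integer(0))
  if (any(s < 0L | s > 65535L)) abort("samples must be 16-bit (0-65535)")
  as.integer(rbind(s %/% 256L, s %% 256L))
}
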