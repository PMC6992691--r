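# Minimal ZIP archive writer (STORE method, no compression), sufficient for
# the small CSV bundles this package emits and readable by any standard
# unzip tool. Implements the classic PKZIP local-header / central-directory
# layout with CRC-32 checksums.

crc32_table <- local({
  tab <- integer(256)
  poly <- -306674912L  # 0xEDB88320 as a signed 32-bit integer
  for (i in 0:255) {
    crc <- i
    for (k in 1:8) {
      crc <- if (bitwAnd(crc, 1L) != 0L) {
        bitwXor(bitwShiftR(crc, 1L), poly)
      } else {
        bitwShiftR(crc, 1L)
      }
    }
    tab[i + 1L] <- crc
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L  # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(crc, b), 255L)
    crc <- bitwXor(bitwShiftR(crc, 8L), crc32_table[idx + 1L])
  }
  bitwXor(crc, -1L)
}

uint16_bytes <- function(x) {
  as.raw(c(bitwAnd(x, 255L), bitwAnd(bitwShiftR(x, 8L), 255L)))
}

uint32_bytes <- function(x) {
  # x may be a signed 32-bit integer (CRC) or a non-negative double
  if (is.integer(x) && x < 0) {
    as.raw(c(bitwAnd(x, 255L), bitwAnd(bitwShiftR(x, 8L), 255L),
             bitwAnd(bitwShiftR(x, 16L), 255L),
             bitwAnd(bitwShiftR(x, 24L), 255L)))
  } else {
    x <- as.numeric(x)
    as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
             (x %/% 16777216) %% 256))
  }
}

#' Write files into a zip archive
#'
#' Stores the given files uncompressed in a single standard zip archive.
#'
#' @param files Paths of files to include.
#' @param zipfile Output archive path.
#' @param names Archive member names; basenames of `files` by default.
#' @return Invisibly, `zipfile`.
#' @export
write_zip <- function(files, zipfile, names = basename(files)) {
  stopifnot(length(files) == length(names), all(file.exists(files)))
  con <- file(zipfile, "wb")
  on.exit(close(con))
  offsets <- numeric(length(files))
  entries <- vector("list", length(files))
  pos <- 0
  for (i in seq_along(files)) {
    data <- readBin(files[[i]], "raw", n = file.info(files[[i]])$size)
    crc <- crc32(data)
    nm <- charToRaw(enc2utf8(names[[i]]))
    header <- c(
      as.raw(c(0x50, 0x4b, 0x03, 0x04)),  # local file header signature
      uint16_bytes(20L),                   # version needed
      uint16_bytes(0L),                    # flags
      uint16_bytes(0L),                    # method: store
      uint16_bytes(0L), uint16_bytes(0L),  # dos time/date (fixed: epoch)
      uint32_bytes(crc),
      uint32_bytes(length(data)),          # compressed size
      uint32_bytes(length(data)),          # uncompressed size
      uint16_bytes(length(nm)),
      uint16_bytes(0L)                     # extra length
    )
    offsets[[i]] <- pos
    writeBin(c(header, nm, data), con)
    pos <- pos + length(header) + length(nm) + length(data)
    entries[[i]] <- list(name = nm, crc = crc, size = length(data))
  }
  cd_start <- pos
  cd_size <- 0
  for (i in seq_along(files)) {
    e <- entries[[i]]
    central <- c(
      as.raw(c(0x50, 0x4b, 0x01, 0x02)),  # central directory signature
      uint16_bytes(20L), uint16_bytes(20L),
      uint16_bytes(0L), uint16_bytes(0L),
      uint16_bytes(0L), uint16_bytes(0L),
      uint32_bytes(e$crc),
      uint32_bytes(e$size), uint32_bytes(e$size),
      uint16_bytes(length(e$name)),
      uint16_bytes(0L), uint16_bytes(0L),  # extra, comment
      uint16_bytes(0L),                    # disk number
      uint16_bytes(0L),                    # internal attrs
      uint32_bytes(0),                     # external attrs
      uint32_bytes(offsets[[i]])
    )
    writeBin(c(central, e$name), con)
    cd_size <- cd_size + length(central) + length(e$name)
  }
  eocd <- c(
    as.raw(c(0x50, 0x4b, 0x05, 0x06)),
    uint16_bytes(0L), uint16_bytes(0L),
    uint16_bytes(length(files)), uint16_bytes(length(files)),
    uint32_bytes(cd_size), uint32_bytes(cd_start),
    uint16_bytes(0L)
  )
  writeBin(eocd, con)
  invisible(zipfile)
}
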