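# Minimal deterministic ZIP writer (store method, fixed timestamps).
# Darwin Core Archives are plain zips of small text files; writing them
# directly keeps archives byte-identical across runs and machines, which
# the determinism contract requires and external zip tools do not give.

crc32_env <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (is.null(crc32_env$table)) {
    poly <- -306674912L  # 0xEDB88320 as a signed 32-bit integer
    tab <- integer(256)
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
    crc32_env$table <- tab
  }
  crc32_env$table
}

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L
  ints <- as.integer(bytes)
  for (b in ints) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  crc <- bitwXor(crc, -1L)
  if (crc < 0) crc + 2^32 else as.numeric(crc)
}

le_bytes <- function(x, n) {
  x <- as.numeric(x)
  out <- raw(n)
  for (i in seq_len(n)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

ZIP_DOS_DATE <- (40 * 512) + (1 * 32) + 1  # fixed 2020-01-01, for determinism
ZIP_DOS_TIME <- 0

# entries: named list of raw vectors (name -> file bytes)
write_zip <- function(entries, path) {
  locals <- list()
  centrals <- list()
  offset <- 0
  for (name in names(entries)) {
    data <- entries[[name]]
    nm <- charToRaw(enc2utf8(name))
    crc <- crc32(data)
    common <- c(le_bytes(20, 2),            # version needed
                le_bytes(0x0800, 2),        # flags: UTF-8 names
                le_bytes(0, 2),             # method: stored
                le_bytes(ZIP_DOS_TIME, 2), le_bytes(ZIP_DOS_DATE, 2),
                le_bytes(crc, 4),
                le_bytes(length(data), 4), le_bytes(length(data), 4),
                le_bytes(length(nm), 2), le_bytes(0, 2))
    locals[[name]] <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)), common, nm, data)
    centrals[[name]] <- c(as.raw(c(0x50, 0x4b, 0x01, 0x02)),
                          le_bytes(20, 2), common,
                          le_bytes(0, 2),  # comment len
                          le_bytes(0, 2),  # disk number
                          le_bytes(0, 2),  # internal attrs
                          le_bytes(0, 4),  # external attrs
                          le_bytes(offset, 4), nm)
    offset <- offset + length(locals[[name]])
  }
  central <- do.call(c, unname(centrals))
  eocd <- c(as.raw(c(0x50, 0x4b, 0x05, 0x06)),
            le_bytes(0, 2), le_bytes(0, 2),
            le_bytes(length(entries), 2), le_bytes(length(entries), 2),
            le_bytes(length(central), 4), le_bytes(offset, 4),
            le_bytes(0, 2))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(do.call(c, unname(locals)), con)
  writeBin(central, con)
  writeBin(eocd, con)
  invisible(path)
}
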