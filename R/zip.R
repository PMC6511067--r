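# Minimal ZIP archive writer (stored entries, no compression), used for the
# Flapjack .fjzip container. Deterministic: a fixed DOS timestamp is written
# so identical inputs produce byte-identical archives. Readable by
# utils::unzip and any standard zip tool.

.crc_env <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (!is.null(.crc_env$tab)) return(.crc_env$tab)
  t <- integer(256)
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      lsb <- bitwAnd(c, 1L)
      c <- bitwAnd(bitwShiftR(c, 1L), 2147483647L)  # force logical shift
      if (lsb == 1L) c <- bitwXor(c, -306674912L)   # 0xEDB88320 as signed int
    }
    t[i + 1] <- c
  }
  .crc_env$tab <- t
  t
}

# Table-driven CRC-32 (IEEE) over a raw vector, in signed 32-bit space; the
# result's two's-complement bytes are what the ZIP format stores.
crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L
  for (b in as.integer(bytes)) {
    crc <- bitwXor(bitwAnd(bitwShiftR(crc, 8L), 16777215L),
                   tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

ZIP_DOS_TIME <- 0x7000L                                            # 14:00:00
ZIP_DOS_DATE <- bitwOr(bitwOr(bitwShiftL(40L, 9L), bitwShiftL(1L, 5L)), 1L)  # 2020-01-01

#' Write a stored (uncompressed) ZIP archive
#'
#' @param path output archive path.
#' @param members named list: member file name -> character vector of lines
#'   (joined with newlines) or a raw vector.
#' @return invisibly, the archive path.
#' @export
write_zip <- function(path, members) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(members)
  offsets <- crcs <- sizes <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    data <- members[[i]]
    if (!is.raw(data)) data <- charToRaw(paste0(paste(data, collapse = "\n"), "\n"))
    name <- charToRaw(names(members)[i])
    crcs[i] <- crc32(data)
    sizes[i] <- length(data)
    offsets[i] <- pos
    header <- c(u32(0x04034b50L), u16(20L), u16(0L), u16(0L),
                u16(ZIP_DOS_TIME), u16(ZIP_DOS_DATE), u32(crcs[i]),
                u32(sizes[i]), u32(sizes[i]), u16(length(name)), u16(0L))
    writeBin(c(header, name, data), con)
    pos <- pos + length(header) + length(name) + length(data)
  }
  cd_start <- pos
  for (i in seq_len(n)) {
    name <- charToRaw(names(members)[i])
    entry <- c(u32(0x02014b50L), u16(20L), u16(20L), u16(0L), u16(0L),
               u16(ZIP_DOS_TIME), u16(ZIP_DOS_DATE), u32(crcs[i]),
               u32(sizes[i]), u32(sizes[i]), u16(length(name)), u16(0L),
               u16(0L), u16(0L), u16(0L), u32(0L), u32(offsets[i]))
    writeBin(c(entry, name), con)
    pos <- pos + length(entry) + length(name)
  }
  eocd <- c(u32(0x06054b50L), u16(0L), u16(0L), u16(n), u16(n),
            u32(pos - cd_start), u32(cd_start), u16(0L))
  writeBin(eocd, con)
  invisible(path)
}
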