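## Minimal RIFF/AVI container support for uncompressed 24-bit RGB ("DIB ")
## streams -- the interchange format of uncompressed color HSV recordings.
## Only BI_RGB (biCompression == 0) video is decodable; anything else is a
## format error, since no codec is available.

readUint32 <- function(con) readBin(con, "integer", 1L, size = 4L,
                                    endian = "little")

writeUint32 <- function(con, x) writeBin(as.integer(x), con, size = 4L,
                                         endian = "little")

writeFourCC <- function(con, s) writeChar(s, con, nchars = 4L, eos = NULL)

## Decode one BI_RGB DIB frame payload (BGR, bottom-up, 4-byte padded rows)
decodeDIB <- function(raw, width, height) {
  rowBytes <- ((3L * width + 3L) %/% 4L) * 4L
  v <- as.integer(raw)
  m <- matrix(v, nrow = rowBytes)[seq_len(3L * width), , drop = FALSE]
  a <- array(m, dim = c(3L, width, height))  # channel (BGR), col, row
  a <- aperm(a, c(3L, 2L, 1L))               # row, col, channel
  a <- a[rev(seq_len(height)), , c(3L, 2L, 1L), drop = FALSE]
  a
}

encodeDIB <- function(frame) {
  height <- dim(frame)[1]; width <- dim(frame)[2]
  a <- frame[rev(seq_len(height)), , c(3L, 2L, 1L), drop = FALSE]
  a <- aperm(a, c(3L, 2L, 1L))               # channel (BGR), col, row
  m <- matrix(as.integer(round(a)), nrow = 3L * width)
  rowBytes <- ((3L * width + 3L) %/% 4L) * 4L
  if (rowBytes > 3L * width)
    m <- rbind(m, matrix(0L, rowBytes - 3L * width, height))
  as.raw(as.vector(m))
}

#' Read an uncompressed RGB AVI file
#'
#' Decodes a RIFF/AVI container whose single video stream is uncompressed
#' 24-bit RGB (`BI_RGB` device-independent bitmaps). Compressed or non-RGB
#' streams raise an error naming the compression tag found.
#'
#' @param path path to the AVI file.
#' @return list with `frames` (`H x W x 3 x T` integer array, 0--255) and
#'   `fps`.
#' @keywords internal
readAVI <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(magic, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readUint32(con)
  form <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(form, "AVI ")) stop("not an AVI file: ", path, call. = FALSE)

  width <- height <- NA_integer_; compression <- NA_integer_
  rate <- scale <- NA_real_; microSec <- NA_real_
  framesRaw <- list()

  parseChunks <- function(end) {
    while (seek(con, where = NA) < end - 7L) {
      cc <- readChar(con, 4L, useBytes = TRUE)
      len <- readUint32(con)
      start <- seek(con, where = NA)
      if (identical(cc, "LIST")) {
        readChar(con, 4L, useBytes = TRUE)  # list type; descend
        parseChunks(start + len)
      } else if (identical(cc, "avih")) {
        hdr <- readBin(con, "integer", len %/% 4L, size = 4L,
                       endian = "little")
        microSec <<- hdr[1]
      } else if (identical(cc, "strh")) {
        fccType <- readChar(con, 4L, useBytes = TRUE)
        if (identical(fccType, "vids")) {
          readChar(con, 4L, useBytes = TRUE)  # handler
          hdr <- readBin(con, "integer", (len - 8L) %/% 4L, size = 4L,
                         endian = "little")
          scale <<- hdr[4]; rate <<- hdr[5]
        }
      } else if (identical(cc, "strf") && is.na(width)) {
        hdr <- readBin(con, "integer", min(len %/% 4L, 10L), size = 4L,
                       endian = "little")
        width <<- hdr[2]; height <<- abs(hdr[3])
        bitCount <- hdr[4] %/% 65536L
        compression <<- hdr[5]
        if (bitCount != 24L)
          stop("unsupported AVI bit depth (", bitCount,
               "); only 24-bit RGB is supported", call. = FALSE)
      } else if (grepl("^..d[bc]$", cc)) {
        framesRaw[[length(framesRaw) + 1L]] <<- readBin(con, "raw", len)
      }
      # chunks are word-aligned
      seek(con, where = start + len + (len %% 2L))
    }
  }
  parseChunks(sz)

  if (is.na(width)) stop("no video stream header found in ", path,
                         call. = FALSE)
  if (!identical(compression, 0L))
    stop("AVI stream is not uncompressed RGB (biCompression = ", compression,
         "); cannot decode", call. = FALSE)
  fpsVal <- if (!is.na(rate) && !is.na(scale) && scale > 0) rate / scale
            else if (!is.na(microSec) && microSec > 0) 1e6 / microSec
            else 4000
  arr <- array(0L, dim = c(height, width, 3L, length(framesRaw)))
  for (i in seq_along(framesRaw)) {
    expected <- ((3L * width + 3L) %/% 4L) * 4L * height
    if (length(framesRaw[[i]]) < expected)
      stop("AVI frame ", i - 1L, " is truncated", call. = FALSE)
    arr[, , , i] <- decodeDIB(framesRaw[[i]], width, height)
  }
  list(frames = arr, fps = fpsVal)
}

#' Write an uncompressed RGB AVI file
#'
#' @param frames `H x W x 3 x T` array, values 0--255.
#' @param path output path.
#' @param fps frame rate to record in the headers.
#' @return invisibly, `path`.
#' @keywords internal
writeAVI <- function(frames, path, fps = 4000) {
  d <- dim(frames)
  height <- d[1]; width <- d[2]; n <- d[4]
  rowBytes <- ((3L * width + 3L) %/% 4L) * 4L
  frameBytes <- rowBytes * height

  con <- file(path, "wb")
  on.exit(close(con))

  strfLen <- 40L
  strhLen <- 56L
  avihLen <- 56L
  strlLen <- 4L + 8L + strhLen + 8L + strfLen
  hdrlLen <- 4L + 8L + avihLen + 8L + strlLen
  moviLen <- 4L + n * (8L + frameBytes)
  idxLen <- 16L * n
  riffLen <- 4L + 8L + hdrlLen + 8L + moviLen + 8L + idxLen

  writeFourCC(con, "RIFF"); writeUint32(con, riffLen)
  writeFourCC(con, "AVI ")

  writeFourCC(con, "LIST"); writeUint32(con, hdrlLen)
  writeFourCC(con, "hdrl")
  writeFourCC(con, "avih"); writeUint32(con, avihLen)
  writeUint32(con, round(1e6 / fps))       # dwMicroSecPerFrame
  writeUint32(con, frameBytes * fps)       # dwMaxBytesPerSec
  writeUint32(con, 0L)                     # padding granularity
  writeUint32(con, 16L)                    # AVIF_HASINDEX
  writeUint32(con, n)
  writeUint32(con, 0L)                     # initial frames
  writeUint32(con, 1L)                     # streams
  writeUint32(con, frameBytes)             # suggested buffer
  writeUint32(con, width); writeUint32(con, height)
  for (i in 1:4) writeUint32(con, 0L)

  writeFourCC(con, "LIST"); writeUint32(con, strlLen)
  writeFourCC(con, "strl")
  writeFourCC(con, "strh"); writeUint32(con, strhLen)
  writeFourCC(con, "vids"); writeFourCC(con, "DIB ")
  writeUint32(con, 0L); writeUint32(con, 0L); writeUint32(con, 0L)
  writeUint32(con, 1L)                     # dwScale
  writeUint32(con, round(fps))             # dwRate
  writeUint32(con, 0L)                     # start
  writeUint32(con, n)                      # length
  writeUint32(con, frameBytes)             # buffer size
  writeUint32(con, -1L)                    # quality
  writeUint32(con, 0L)                     # sample size
  writeUint32(con, 0L); writeUint32(con, 0L)  # rcFrame

  writeFourCC(con, "strf"); writeUint32(con, strfLen)
  writeUint32(con, 40L)                    # biSize
  writeUint32(con, width); writeUint32(con, height)
  writeUint32(con, 1L + 24L * 65536L)      # planes + bitcount
  writeUint32(con, 0L)                     # BI_RGB
  writeUint32(con, frameBytes)
  for (i in 1:4) writeUint32(con, 0L)

  writeFourCC(con, "LIST"); writeUint32(con, moviLen)
  writeFourCC(con, "movi")
  offsets <- integer(n)
  pos <- 4L
  for (i in seq_len(n)) {
    offsets[i] <- pos
    writeFourCC(con, "00db"); writeUint32(con, frameBytes)
    writeBin(encodeDIB(frames[, , , i]), con)
    pos <- pos + 8L + frameBytes
  }

  writeFourCC(con, "idx1"); writeUint32(con, idxLen)
  for (i in seq_len(n)) {
    writeFourCC(con, "00db")
    writeUint32(con, 16L)                  # AVIIF_KEYFRAME
    writeUint32(con, offsets[i])
    writeUint32(con, frameBytes)
  }
  invisible(path)
}
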