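#' Read a (possibly gzip-compressed) FASTA file into an indexable text
#'
#' All record sequences are concatenated in file order into one text, with
#' no separators between records (suffixes may span record joins, matching
#' how whole genomes are indexed as a single text). Preprocessing mirrors
#' common practice for genome indexing: `drop_n` removes every `N`/`n`
#' symbol (runs of `N` mark unresolved assembly regions), and `unmask`
#' maps soft-masked lowercase to uppercase.
#'
#' @param path FASTA file, plain or gzip-compressed.
#' @param drop_n Remove all `N`/`n` symbols.
#' @param unmask Uppercase soft-masked (lowercase) symbols.
#' @param allow_any Accept any byte; otherwise non-IUPAC nucleotide
#'   symbols are an error.
#' @param terminator Terminator byte appended after concatenation.
#' @return A `capssa_text` with extra fields `offsets` (0-based start of
#'   each record in the concatenated text, after preprocessing),
#'   `record_names`, and `dropped_n` (count of removed symbols).
#' @export
read_fasta_text <- function(path, drop_n = FALSE, unmask = FALSE,
                            allow_any = FALSE, terminator = as.raw(0L)) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L)
    stop("empty FASTA file: ", path, call. = FALSE)
  chars <- as.character(seqs)
  dropped <- 0L
  pieces <- lapply(chars, function(s) {
    r <- charToRaw(s)
    if (unmask) {
      low <- r >= charToRaw("a") & r <= charToRaw("z")
      r[low] <- as.raw(as.integer(r[low]) - 32L)
    }
    if (drop_n) {
      isn <- r == charToRaw("N") | r == charToRaw("n")
      dropped <<- dropped + sum(isn)
      r <- r[!isn]
    }
    r
  })
  lens <- vapply(pieces, length, integer(1))
  body <- unlist(pieces, use.names = FALSE)
  if (is.null(body)) body <- raw(0)
  if (!allow_any && length(body)) {
    iupac <- charToRaw("ACGTURYSWKMBDHVNacgturyswkmbdhvn.-")
    bad <- !(body %in% iupac)
    if (any(bad))
      stop(sprintf("non-IUPAC symbol '%s' in %s (use allow_any to accept)",
                   rawToChar(body[which(bad)[1L]]), path), call. = FALSE)
  }
  text <- build_text(body, terminator = terminator)
  text$offsets <- as.integer(cumsum(c(0L, lens[-length(lens)])))
  text$record_names <- names(seqs)
  text$dropped_n <- as.integer(dropped)
  text
}

write_uint <- function(con, v, w) {
  v <- as.numeric(v)
  if (w == 4L) {
    writeBin(as.integer(v), con, size = 4L, endian = "little")
  } else {
    lo <- v %% 4294967296
    hi <- v %/% 4294967296
    lo <- ifelse(lo >= 2147483648, lo - 4294967296, lo)
    iv <- integer(2L * length(v))
    iv[seq(1L, by = 2L, length.out = length(v))] <- as.integer(lo)
    iv[seq(2L, by = 2L, length.out = length(v))] <- as.integer(hi)
    writeBin(iv, con, size = 4L, endian = "little")
  }
}

read_uint <- function(con, count, w) {
  if (w == 4L) {
    v <- as.numeric(readBin(con, "integer", n = count, size = 4L,
                            endian = "little"))
    v[v < 0] <- v[v < 0] + 4294967296
    v
  } else {
    iv <- as.numeric(readBin(con, "integer", n = 2L * count, size = 4L,
                             endian = "little"))
    iv[iv < 0] <- iv[iv < 0] + 4294967296
    iv[seq(1L, by = 2L, length.out = count)] +
      4294967296 * iv[seq(2L, by = 2L, length.out = count)]
  }
}

#' Write SA and LCP arrays in the raw on-disk index format
#'
#' Writes `<prefix>.sa` and `<prefix>.lcp` as fixed-width little-endian
#' unsigned integers, plus a `<prefix>.json` sidecar describing the index
#' (length, width, configuration echo, text checksum, statistics). The
#' format round-trips losslessly through [read_index()].
#'
#' @param sa,lcp The arrays (0-based positions / symbol counts).
#' @param prefix Output path prefix.
#' @param w Integer width in bytes: 4, 8 or `"auto"` (4 while every value
#'   fits in 32 bits).
#' @param sidecar Named list merged into the JSON sidecar (configuration
#'   echo, stats, provenance).
#' @return Invisibly, the sidecar list as written.
#' @export
write_index <- function(sa, lcp, prefix, w = "auto", sidecar = list()) {
  n <- length(sa)
  stopifnot(length(lcp) == n)
  maxv <- max(0, as.numeric(sa), as.numeric(lcp), n)
  if (identical(w, "auto")) w <- if (maxv < 4294967296) 4L else 8L
  w <- as.integer(w)
  stopifnot(w %in% c(4L, 8L))
  if (w == 4L && maxv >= 4294967296)
    stop("values overflow 4-byte width; use w = 8", call. = FALSE)
  for (part in list(list(ext = ".sa", v = sa), list(ext = ".lcp", v = lcp))) {
    con <- file(paste0(prefix, part$ext), "wb")
    write_uint(con, part$v, w)
    close(con)
  }
  side <- modifyList(list(n = n, width = w), sidecar)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(side)
}

#' @rdname write_index
#' @param index A `capssa_index` from [capssa_build()]; convenience wrapper
#'   writing its arrays plus a full sidecar.
#' @param text The `capssa_text` the index was built from (for checksum
#'   and record offsets).
#' @export
write_index_files <- function(index, prefix, text = NULL, w = NULL) {
  stopifnot(inherits(index, "capssa_index"))
  cfg <- index$config
  side <- list(
    config = list(p = cfg$p, s = cfg$s, k = cfg$k,
                  prefix_limit = cfg$prefix_limit, seed = cfg$seed),
    stats = index$stats,
    peak_aux = index$peak_aux,
    checksum = index$checksum,
    partitions = as.numeric(index$layout$cumulative)
  )
  if (!is.null(text)) {
    if (!is.null(text$offsets)) side$record_offsets <- text$offsets
    if (!is.null(text$dropped_n)) side$dropped_n <- text$dropped_n
  }
  w <- if (is.null(w)) if (identical(cfg$width, "auto")) "auto" else cfg$width
       else w
  write_index(index$sa, index$lcp, prefix, w = w, sidecar = side)
}

#' Read an index written by [write_index()]
#'
#' @param prefix Path prefix used at write time.
#' @return List with `sa`, `lcp` (numeric vectors) and `sidecar`.
#' @export
read_index <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  n <- as.integer(side$n)
  w <- as.integer(side$width)
  out <- list()
  for (part in c("sa", "lcp")) {
    con <- file(paste0(prefix, ".", part), "rb")
    out[[part]] <- read_uint(con, n, w)
    close(con)
  }
  out$sidecar <- side
  out
}
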