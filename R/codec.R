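#' Quaternary codec: binary data to indexed oligos and back
#'
#' The storage code is the plain quaternary map 00-A, 01-T, 10-G, 11-C,
#' applied big-endian within each byte and left to right across the payload.
#' Each oligo carries an address index (default 8 nt, i.e. up to 4^8 = 65,536
#' oligos) followed by a data payload (default 112 nt = 28 bytes), for a
#' total design length of 120 nt and a logical density of 2 bits/nt in the
#' payload. No biochemical constraints (GC content, homopolymers) and no
#' error-correcting redundancy are applied: the code is deliberately the
#' simplest possible, so that all error correction is left to alignment and
#' voting downstream.
#'
#' @name codec
NULL

QUAT_MAP <- c("A", "T", "G", "C") # value 0,1,2,3

#' Encode a bit string as DNA bases
#'
#' Maps consecutive 2-bit groups to bases by 00-A, 01-T, 10-G, 11-C.
#'
#' @param bits A single string over `{0,1}` of even length (may be empty).
#' @return A DNA string of `nchar(bits)/2` bases.
#' @examples
#' encode_bits("00011011") # "ATGC"
#' @seealso [decode_bases()] for the inverse map.
#' @export
encode_bits <- function(bits) {
  if (length(bits) != 1L || !is.character(bits) || is.na(bits)) {
    stop("bits must be a single character string", call. = FALSE)
  }
  if (!nzchar(bits)) return("")
  if (grepl("[^01]", bits)) stop("bits may contain only 0 and 1", call. = FALSE)
  n <- nchar(bits)
  if (n %% 2L != 0L) stop("bit string length must be even", call. = FALSE)
  v <- utf8ToInt(bits) - 48L
  hi <- v[seq(1L, n, by = 2L)]
  lo <- v[seq(2L, n, by = 2L)]
  paste(QUAT_MAP[2L * hi + lo + 1L], collapse = "")
}

#' Decode DNA bases to a bit string
#'
#' Exact inverse of [encode_bits()]. Gap characters are rejected: callers
#' must degap alignment rows before decoding.
#'
#' @param bases A DNA string over `{A,C,G,T}` (may be empty).
#' @return A string over `{0,1}` of `2 * nchar(bases)` bits.
#' @examples
#' decode_bases("ATGC") # "00011011"
#' @export
decode_bases <- function(bases) {
  if (length(bases) != 1L || !is.character(bases) || is.na(bases)) {
    stop("bases must be a single character string", call. = FALSE)
  }
  if (!nzchar(bases)) return("")
  if (grepl("[^ACGT]", bases)) {
    stop("bases may contain only A, C, G, T (strip gaps first)", call. = FALSE)
  }
  vals <- c(A = 0L, T = 1L, G = 2L, C = 3L)[chars(bases)]
  paste0(vals %/% 2L, vals %% 2L, collapse = "")
}

# byte vector (integers 0..255) -> DNA string, 4 bases per byte
#' @noRd
bytes_to_bases <- function(bytes) {
  if (length(bytes) == 0L) return("")
  q <- rbind(
    bitwAnd(bitwShiftR(bytes, 6L), 3L),
    bitwAnd(bitwShiftR(bytes, 4L), 3L),
    bitwAnd(bitwShiftR(bytes, 2L), 3L),
    bitwAnd(bytes, 3L)
  )
  paste(QUAT_MAP[as.vector(q) + 1L], collapse = "")
}

#' @noRd
bases_to_bytes <- function(bases) {
  if (!nzchar(bases)) return(raw(0))
  if (nchar(bases) %% 4L != 0L) {
    stop("base string length must be a multiple of 4 to form whole bytes", call. = FALSE)
  }
  vals <- unname(c(A = 0L, T = 1L, G = 2L, C = 3L)[chars(bases)])
  m <- matrix(vals, nrow = 4L)
  as.raw(m[1L, ] * 64L + m[2L, ] * 16L + m[3L, ] * 4L + m[4L, ])
}

# index_id -> index_len-base prefix, big-endian 2-bit groups
#' @noRd
encode_index <- function(index_id, index_len) {
  shifts <- seq.int(2L * (index_len - 1L), 0L, by = -2L)
  paste(QUAT_MAP[bitwAnd(bitwShiftR(index_id, shifts), 3L) + 1L], collapse = "")
}

#' @noRd
decode_index <- function(prefix) {
  vals <- unname(c(A = 0L, T = 1L, G = 2L, C = 3L)[chars(prefix)])
  sum(vals * 4L^rev(seq_along(vals) - 1L))
}

#' Split binary data into indexed oligos
#'
#' Splits `data` into payload-sized blocks (28 bytes for the 120/8 defaults),
#' zero-pads the final block, and prepends each block's big-endian quaternary
#' index. The manifest records the original byte length and padding so that
#' [recover_bytes()] can restore the file exactly.
#'
#' @param data A raw vector, or a single character string (encoded as UTF-8).
#' @param L Total oligo length in bases (default 120).
#' @param index_len Index prefix length in bases (default 8).
#' @return An object of class `encoded_file`: a list with `oligos`, a tibble
#'   with columns `index_id` and `sequence`, and `manifest`, a list with
#'   entries `L`, `index_len`, `payload_len`, `original_byte_length`,
#'   `padding_bytes` and `n_oligos`.
#' @examples
#' enc <- make_oligos(as.raw(1:29))
#' enc$oligos
#' @export
make_oligos <- function(data, L = 120L, index_len = 8L) {
  if (is.character(data) && length(data) == 1L) data <- charToRaw(data)
  if (!is.raw(data)) stop("data must be a raw vector or a single string", call. = FALSE)
  if (length(data) == 0L) stop("data must be non-empty", call. = FALSE)
  L <- as.integer(L); index_len <- as.integer(index_len)
  if (index_len < 1L || L <= index_len) stop("need L > index_len >= 1", call. = FALSE)
  payload_len <- L - index_len
  if (payload_len %% 4L != 0L) {
    stop("payload length (L - index_len) must be a multiple of 4 bases", call. = FALSE)
  }
  block_bytes <- payload_len %/% 4L
  n_oligos <- ceiling(length(data) / block_bytes)
  if (n_oligos > 4^index_len) {
    stop("data needs ", n_oligos, " oligos but the ", index_len,
         "-base index addresses only ", 4^index_len, call. = FALSE)
  }
  padding <- n_oligos * block_bytes - length(data)
  padded <- as.integer(c(data, raw(padding)))
  seqs <- vapply(seq_len(n_oligos) - 1L, function(i) {
    block <- padded[(i * block_bytes + 1L):((i + 1L) * block_bytes)]
    paste0(encode_index(i, index_len), bytes_to_bases(block))
  }, character(1))
  structure(
    list(
      oligos = tibble::tibble(index_id = seq_len(n_oligos) - 1L, sequence = seqs),
      manifest = list(
        L = L, index_len = index_len, payload_len = payload_len,
        original_byte_length = length(data), padding_bytes = as.integer(padding),
        n_oligos = as.integer(n_oligos)
      )
    ),
    class = "encoded_file"
  )
}

#' @export
print.encoded_file <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<encoded_file> %d oligos of %d nt (%d nt index + %d nt payload), %d bytes (%d padding)\n",
    m$n_oligos, m$L, m$index_len, m$payload_len, m$original_byte_length, m$padding_bytes
  ))
  print(x$oligos, ...)
  invisible(x)
}

#' Reassemble the original bytes from per-index consensus sequences
#'
#' @param consensuses Consensus sequences: a tibble with columns `index_id`
#'   and `sequence`, or a character vector named by index id.
#' @param manifest The manifest from [make_oligos()] (or read back from JSON).
#' @return A raw vector identical to the encoded input.
#' @examples
#' enc <- make_oligos(charToRaw("hello, storage"))
#' identical(recover_bytes(enc$oligos, enc$manifest), charToRaw("hello, storage"))
#' @export
recover_bytes <- function(consensuses, manifest) {
  if (is.character(consensuses)) {
    consensuses <- tibble::tibble(
      index_id = as.integer(names(consensuses)), sequence = unname(consensuses)
    )
  }
  need <- seq_len(manifest$n_oligos) - 1L
  missing <- setdiff(need, consensuses$index_id)
  if (length(missing) > 0L) {
    stop("incomplete file: missing index id(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ord <- consensuses[match(need, consensuses$index_id), ]
  payloads <- vapply(ord$sequence, function(s) {
    assert_dna(s, "consensus")
    if (nchar(s) != manifest$L) {
      stop("consensus length ", nchar(s), " != oligo length ", manifest$L,
           " (fix or pad the consensus before decoding)", call. = FALSE)
    }
    substr(s, manifest$index_len + 1L, manifest$L)
  }, character(1), USE.NAMES = FALSE)
  bytes <- bases_to_bytes(paste(payloads, collapse = ""))
  bytes[seq_len(manifest$original_byte_length)]
}

#' Write an encoded file as FASTA plus a JSON manifest
#'
#' Record ids are zero-padded index ids, so FASTA order and lexicographic
#' order agree.
#'
#' @param encoded An `encoded_file` from [make_oligos()].
#' @param fasta Path of the FASTA file to write.
#' @param manifest Path of the JSON manifest to write (default: `fasta` with
#'   a `.json` extension). Use `NULL` to skip.
#' @return `fasta`, invisibly.
#' @export
write_oligos <- function(encoded, fasta,
                         manifest = paste0(tools::file_path_sans_ext(fasta), ".json")) {
  stopifnot(inherits(encoded, "encoded_file"))
  width <- nchar(format(max(encoded$oligos$index_id)))
  ids <- formatC(encoded$oligos$index_id, width = max(width, 4L), flag = "0")
  write_fasta(tibble::tibble(id = ids, sequence = encoded$oligos$sequence), fasta)
  if (!is.null(manifest)) {
    jsonlite::write_json(encoded$manifest, manifest, auto_unbox = TRUE)
  }
  invisible(fasta)
}

#' Read an encoded file back from FASTA + manifest
#'
#' @param fasta Path to a FASTA of oligos whose record ids are (zero-padded)
#'   index ids.
#' @param manifest Path to the JSON manifest written by [write_oligos()].
#' @return An `encoded_file` object.
#' @export
read_oligos <- function(fasta, manifest) {
  recs <- read_fasta(fasta)
  man <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  man <- lapply(man, function(v) if (is.numeric(v)) as.integer(v) else v)
  oligos <- tibble::tibble(
    index_id = as.integer(recs$id), sequence = recs$sequence
  )
  oligos <- dplyr::arrange(oligos, .data$index_id)
  structure(list(oligos = oligos, manifest = man), class = "encoded_file")
}
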