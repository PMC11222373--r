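#' Diagnosis vocabulary at the ICD-9 two-digit sub-chapter level
#'
#' A `dx_vocab` maps diagnosis sub-chapter codes and five special tokens
#' (pad, `[CLS]`, `[SEP]`, `[MASK]`, `OOV`) to contiguous integer ids.
#' The pad token always has id 0 so that padded positions can be masked by
#' a simple zero test; codes follow the special tokens in lexicographic
#' order, which makes the id assignment independent of the input ordering.
#'
#' @param code_set Character vector (treated as a set) of two-character
#'   sub-chapter codes, e.g. `"48"`, `"V3"`.
#' @return An object of class `dx_vocab` with fields `codes`,
#'   `special_tokens`, `code_to_id` (named integer vector) and `id_to_code`
#'   (character vector indexed by `id + 1`), plus `size` (total vocabulary
#'   size) and the ids of the special tokens (`pad_id`, `cls_id`, `sep_id`,
#'   `mask_id`, `oov_id`), all 0-based.
#' @examples
#' v <- build_vocabulary(c("48", "49", "52"))
#' v$size                 # 3 codes + 5 special tokens
#' encode_code(v, "48")
#' encode_code(v, "zz")   # unknown -> OOV id
#' @export
build_vocabulary <- function(code_set) {
  code_set <- unique(as.character(code_set))
  if (length(code_set) == 0) {
    stop("`code_set` must contain at least one sub-chapter code.", call. = FALSE)
  }
  bad <- code_set[nchar(code_set) != 2L | is.na(code_set)]
  if (length(bad) > 0) {
    stop("Malformed sub-chapter codes (must be exactly two characters): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  specials <- c("[PAD]", "[CLS]", "[SEP]", "[MASK]", "[OOV]")
  codes <- sort(code_set, method = "radix")
  tokens <- c(specials, codes)
  ids <- seq_along(tokens) - 1L
  code_to_id <- stats::setNames(ids, tokens)
  out <- structure(
    list(
      codes = codes,
      special_tokens = specials,
      code_to_id = code_to_id,
      id_to_code = tokens,
      size = length(tokens),
      pad_id = 0L, cls_id = 1L, sep_id = 2L, mask_id = 3L, oov_id = 4L,
      n_special = 5L
    ),
    class = "dx_vocab"
  )
  out
}

#' @export
print.dx_vocab <- function(x, ...) {
  cat("<dx_vocab> ", length(x$codes), " codes + ", length(x$special_tokens),
      " special tokens = ", x$size, " ids\n", sep = "")
  invisible(x)
}

#' @export
tidy.dx_vocab <- function(x, ...) {
  tibble::tibble(
    id = seq_len(x$size) - 1L,
    token = x$id_to_code,
    type = rep(c("special", "code"), c(x$n_special, length(x$codes)))
  )
}

#' Truncate a full ICD-9 code to its two-digit sub-chapter
#'
#' Takes the category part of an ICD-9 code (the part before any decimal
#' point) and returns its first two characters; letter prefixes of
#' supplementary classifications (V, E) are retained, so `"V30"` maps to
#' `"V3"`. Vectorized.
#'
#' @param icd9_code Character vector of ICD-9 codes (3-5 characters, with
#'   or without a decimal point).
#' @return Character vector of two-character sub-chapter codes.
#' @examples
#' truncate_to_subchapter(c("486", "48611", "V30", "003.0"))
#' @export
truncate_to_subchapter <- function(icd9_code) {
  icd9_code <- as.character(icd9_code)
  category <- sub("\\..*$", "", icd9_code)
  if (any(is.na(category) | nchar(category) < 2L)) {
    bad <- icd9_code[is.na(category) | nchar(category) < 2L]
    stop("ICD-9 codes must have at least two leading characters: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  substr(category, 1L, 2L)
}

#' Encode diagnosis codes to token ids
#'
#' Unknown codes map to the OOV id rather than raising an error, so the
#' encoding is total over arbitrary strings.
#'
#' @param vocab A [build_vocabulary()] object.
#' @param code Character vector of sub-chapter codes.
#' @return Integer vector of 0-based token ids.
#' @export
encode_code <- function(vocab, code) {
  stopifnot(inherits(vocab, "dx_vocab"))
  id <- unname(vocab$code_to_id[as.character(code)])
  id[is.na(id)] <- vocab$oov_id
  as.integer(id)
}

#' Decode token ids back to token strings
#'
#' @param vocab A [build_vocabulary()] object.
#' @param id Integer vector of 0-based token ids.
#' @return Character vector of tokens (codes or special-token strings).
#' @export
decode_id <- function(vocab, id) {
  stopifnot(inherits(vocab, "dx_vocab"))
  id <- as.integer(id)
  if (any(id < 0L | id >= vocab$size)) {
    stop("Token id out of range [0, ", vocab$size - 1L, "].", call. = FALSE)
  }
  vocab$id_to_code[id + 1L]
}

#' Read and apply an ICD-10 to ICD-9 crosswalk
#'
#' The crosswalk is a user-supplied two-column delimited file (ICD-10 code,
#' ICD-9 code). When an ICD-10 code maps to several ICD-9 codes the
#' first-listed pair wins; later duplicates are kept in the table but
#' ignored by the lookup. Unmapped codes return `NA` so the caller decides
#' whether to drop them or send them to OOV.
#'
#' @param path Path to a delimited text file with two columns.
#' @param sep Field separator (default tab).
#' @return A tibble with columns `icd10`, `icd9` of class `icd_crosswalk`.
#' @export
read_crosswalk <- function(path, sep = "\t") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad) > 0) {
    stop("Malformed crosswalk file at line ", bad[1],
         ": expected two `", sep, "`-separated columns.", call. = FALSE)
  }
  out <- tibble::tibble(
    icd10 = trimws(vapply(parts, `[[`, "", 1L)),
    icd9 = trimws(vapply(parts, `[[`, "", 2L))
  )
  class(out) <- c("icd_crosswalk", class(out))
  out
}

#' @rdname read_crosswalk
#' @param crosswalk A crosswalk tibble (columns `icd10`, `icd9`), e.g. from
#'   [read_crosswalk()].
#' @param code Character vector of ICD-10 codes to map.
#' @return For `map_icd10_to_icd9()`: character vector of ICD-9 codes, `NA`
#'   where no mapping exists.
#' @export
map_icd10_to_icd9 <- function(crosswalk, code) {
  stopifnot(is.data.frame(crosswalk), all(c("icd10", "icd9") %in% names(crosswalk)))
  idx <- match(as.character(code), crosswalk$icd10)
  ifelse(is.na(idx), NA_character_, crosswalk$icd9[idx])
}

#' Serialize / restore a vocabulary as two-column delimited text
#'
#' @param vocab A `dx_vocab`.
#' @param path File path.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "dx_vocab"))
  utils::write.table(
    data.frame(id = seq_len(vocab$size) - 1L, token = vocab$id_to_code),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  tab <- utils::read.table(path, sep = "\t", colClasses = c("integer", "character"))
  tokens <- tab[[2]][order(tab[[1]])]
  build_vocabulary(tokens[-(1:5)])
}

#' Default sub-chapter code universe
#'
#' A deterministic list of two-character sub-chapter codes used by the
#' synthetic generator: the numeric sub-chapters `"00"`-`"99"` followed by
#' supplementary-classification prefixes (`V0`-`V9`, `E0`-`E9`), truncated
#' to `n` codes. With the default `n = 115` this matches the size of the
#' label space used throughout the package.
#'
#' @param n Number of codes (1-120).
#' @return Character vector of length `n`.
#' @export
default_code_set <- function(n = 115L) {
  universe <- c(sprintf("%02d", 0:99), paste0("V", 0:9), paste0("E", 0:9))
  if (n < 1L || n > length(universe)) {
    stop("`n` must be between 1 and ", length(universe), ".", call. = FALSE)
  }
  universe[seq_len(n)]
}
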