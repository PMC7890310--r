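#' Collapse a factor combination into a single composite factor
#'
#' Transforms a combination `S` of categorical columns into one factor whose
#' levels are the *observed* value-tuples of `S`: two patients share a code
#' if and only if they agree on every factor in `S`. Codes are assigned in
#' lexicographic tuple order (first factor most significant), so the mapping
#' is deterministic and the codebook is injective on observed tuples.
#'
#' @param S Character vector of factor names (no duplicates).
#' @param data A data.frame containing the named columns.
#' @return An object of class `composite_factor`: integer `codes` (1-based,
#'   one per row), the `codebook` data.frame mapping codes to value-tuples,
#'   and the combination `S`.
#' @examples
#' d <- data.frame(a = c("x", "x", "y"), b = c(1, 2, 1))
#' cf <- combine(c("a", "b"), d)
#' cf$codes      # 1 2 3
#' cf$codebook   # the three observed tuples
#' @export
combine <- function(S, data) {
  if (anyDuplicated(S)) stop("duplicate factor names in S", call. = FALSE)
  unknown <- setdiff(S, names(data))
  if (length(unknown)) {
    stop("unknown factor name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  enc <- lapply(S, function(nm) int_codes(data[[nm]]))
  raw <- mixed_radix_code(lapply(enc, `[[`, "code"),
                          vapply(enc, `[[`, 0L, "k"))
  observed <- sort(unique(raw))
  codes <- match(raw, observed)
  # decode observed raw codes back into tuples for the codebook
  tuples <- decode_tuples(observed, vapply(enc, `[[`, 0L, "k"))
  codebook <- as.data.frame(lapply(seq_along(S), function(j) {
    enc[[j]]$levels[tuples[, j]]
  }), col.names = S, stringsAsFactors = FALSE)
  codebook <- cbind(code = seq_along(observed), codebook)
  structure(list(codes = codes, k = length(observed),
                 codebook = codebook, S = S),
            class = "composite_factor")
}

# 0-based mixed-radix code with the first factor most significant, returned
# 1-based; ascending numeric order == lexicographic tuple order.
mixed_radix_code <- function(code_list, k) {
  raw <- code_list[[1L]] - 1L
  if (length(k) > 1L) {
    for (j in 2:length(k)) raw <- raw * k[j] + (code_list[[j]] - 1L)
  }
  raw + 1L
}

decode_tuples <- function(raw, k) {
  raw <- raw - 1L
  p <- length(k)
  out <- matrix(0L, nrow = length(raw), ncol = p)
  for (j in p:1) {
    out[, j] <- raw %% k[j] + 1L
    raw <- raw %/% k[j]
  }
  out
}

#' @export
print.composite_factor <- function(x, ...) {
  cat("Composite factor over {", paste(x$S, collapse = ", "), "}: ",
      x$k, " observed value-tuples, n = ", length(x$codes), "\n", sep = "")
  invisible(x)
}
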