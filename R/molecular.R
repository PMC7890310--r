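#' Five-group molecular classification of diffuse glioma
#'
#' Maps the three tumor genetic markers -- IDH mutation (IDH1 or IDH2), TERT
#' promoter mutation, and 1p/19q codeletion -- to the five canonical
#' molecular groups of Eckel-Passow and colleagues, with a residual "Others"
#' group for the three marker combinations outside the taxonomy (all of which
#' carry 1p/19q codeletion without the full triple-positive pattern).
#'
#' The five named groups are: triple-positive (TERT and IDH mutated plus
#' 1p/19q codeleted), TERT+IDH (both mutations without codeletion), IDH-only,
#' TERT-only, and triple-negative.
#'
#' @param idh 0/1 (or logical) IDH mutation status (IDH1 or IDH2).
#' @param tert 0/1 TERT promoter mutation status.
#' @param codel 0/1 1p/19q codeletion status.
#' @return A factor with levels
#'   `Triple-positive, TERT+IDH, IDH-only, TERT-only, Triple-negative, Others`.
#' @examples
#' derive_molecular_group(1, 1, 1)  # Triple-positive
#' derive_molecular_group(0, 0, 0)  # Triple-negative
#' derive_molecular_group(1, 0, 1)  # Others: codeletion outside the taxonomy
#' @export
derive_molecular_group <- function(idh, tert, codel) {
  idh <- as.integer(idh); tert <- as.integer(tert); codel <- as.integer(codel)
  stopifnot(all(idh %in% 0:1), all(tert %in% 0:1), all(codel %in% 0:1))
  n <- max(length(idh), length(tert), length(codel))
  idh <- rep_len(idh, n); tert <- rep_len(tert, n); codel <- rep_len(codel, n)
  out <- rep("Others", n)
  out[idh == 1 & tert == 1 & codel == 1] <- "Triple-positive"
  out[idh == 1 & tert == 1 & codel == 0] <- "TERT+IDH"
  out[idh == 1 & tert == 0 & codel == 0] <- "IDH-only"
  out[idh == 0 & tert == 1 & codel == 0] <- "TERT-only"
  out[idh == 0 & tert == 0 & codel == 0] <- "Triple-negative"
  factor(out, levels = glioma_levels()$mol_group)
}
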