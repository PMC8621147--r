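# Physicochemical calculations: average molecular weight, Bjellqvist
# theoretical pI, residue composition.

#' Physicochemical characteristics of a protein
#'
#' Computes the average molecular weight (sum of average residue masses plus
#' one water), the theoretical isoelectric point (bisection on the
#' Henderson-Hasselbalch net-charge function with the Bjellqvist pK set used
#' by ProtParam), the per-residue composition, and the glutamine, proline and
#' essential-amino-acid percentages.
#'
#' Sequences containing `*` or `X` have no defined mass/charge: MW and pI are
#' refused (returned as NA with a warning) and the composition is computed
#' over the defined residues only.
#'
#' @param protein Amino-acid sequence (non-empty).
#' @param essential Residues counted as essential; the default set includes
#'   histidine.
#' @return List of class `physchem`: `mw` (Da), `pi`, `length`,
#'   `composition` (tibble `residue`, `count`, `pct`), `glutamine_pct`,
#'   `proline_pct`, `essential_pct`.
#' @export
#' @examples
#' ph <- physchem("GG")
#' round(ph$mw, 2)  # 132.12
physchem <- function(protein, essential = ESSENTIAL_AA_DEFAULT) {
  protein <- check_aa(protein, allow_stop = TRUE, allow_x = TRUE)
  if (nchar(protein) == 0L) abort("empty sequence")
  res <- split_chars(protein)
  defined <- res[res %in% names(AA_AVG_MASS)]
  undefined <- length(res) - length(defined)

  counts <- table(factor(defined, levels = names(AA_AVG_MASS)))
  composition <- tibble(
    residue = names(counts),
    count = as.integer(counts),
    pct = 100 * as.integer(counts) / length(defined)
  )

  if (undefined > 0L) {
    warn("sequence contains '*' or 'X'; MW and pI are not defined and composition uses defined residues only")
    mw <- NA_real_
    pi_val <- NA_real_
  } else {
    mw <- sum(AA_AVG_MASS[res]) + WATER_MASS
    pi_val <- isoelectric_point(res)
  }

  pct_of <- function(set) sum(composition$pct[composition$residue %in% set])
  structure(
    list(mw = mw, pi = pi_val, length = length(defined),
         composition = composition,
         glutamine_pct = pct_of("Q"),
         proline_pct = pct_of("P"),
         essential_pct = pct_of(essential)),
    class = "physchem"
  )
}

#' @export
print.physchem <- function(x, ...) {
  cat("<physchem> ", x$length, " aa, MW ",
      ifelse(is.na(x$mw), "NA", format(round(x$mw), big.mark = "")),
      " Da, pI ", ifelse(is.na(x$pi), "NA", sprintf("%.2f", x$pi)), "\n",
      "  Q ", sprintf("%.1f", x$glutamine_pct), "%, P ",
      sprintf("%.1f", x$proline_pct), "%, essential ",
      sprintf("%.1f", x$essential_pct), "%\n", sep = "")
  invisible(x)
}

# net charge of a residue-vector protein at a given pH under the Bjellqvist
# pK set
protein_charge <- function(res, ph) {
  nterm_pk <- PK_NTERM[res[1]]
  if (is.na(nterm_pk)) nterm_pk <- PK_NTERM_DEFAULT
  pos <- 1 / (1 + 10^(ph - nterm_pk))
  for (r in names(PK_SIDE_POS)) {
    k <- sum(res == r)
    if (k) pos <- pos + k / (1 + 10^(ph - PK_SIDE_POS[[r]]))
  }
  neg <- 1 / (1 + 10^(PK_CTERM - ph))
  for (r in names(PK_SIDE_NEG)) {
    k <- sum(res == r)
    if (k) neg <- neg + k / (1 + 10^(PK_SIDE_NEG[[r]] - ph))
  }
  pos - neg
}

# bisection for the pH of zero net charge; tolerance 0.001 pH units
isoelectric_point <- function(res, tol = 0.001) {
  lo <- 0; hi <- 14
  # charge is monotone decreasing in pH
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (protein_charge(res, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
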