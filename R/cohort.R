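# The universal population container: integer counts per (genotype, sex).

#' Sexed cohort of individuals
#'
#' A cohort is a 9 x 2 integer matrix of counts, rows indexed by genotype
#' (see [genotype_table()]) and columns by sex (`"F"`, `"M"`). It represents
#' any life stage (eggs, larvae surviving to pupation, adults).
#'
#' @param counts Optional 9 x 2 matrix of non-negative counts.
#' @return An object of class `sexed_cohort`.
#' @examples
#' x <- empty_cohort()
#' x["RRww", "F"] <- 10
#' cohort_size(x)
#' @export
cohort <- function(counts = NULL) {
  if (is.null(counts)) counts <- matrix(0, N_GENO, 2)
  stopifnot(is.matrix(counts), nrow(counts) == N_GENO, ncol(counts) == 2,
            all(counts >= 0), all(counts == round(counts)))
  dimnames(counts) <- list(genotype = GENO_LABELS, sex = c("F", "M"))
  structure(counts, class = c("sexed_cohort", "matrix", "array"))
}

#' @rdname cohort
#' @export
empty_cohort <- function() cohort()

#' Build a cohort from genotype/sex counts
#'
#' @param r_copies,l_copies Genotype of the individuals added (scalars).
#' @param females,males Counts of each sex.
#' @param base Cohort to add to (default empty).
#' @return A `sexed_cohort`.
#' @export
cohort_of <- function(r_copies, l_copies, females = 0, males = 0,
                      base = empty_cohort()) {
  g <- genotype(r_copies, l_copies)
  base[g, "F"] <- base[g, "F"] + females
  base[g, "M"] <- base[g, "M"] + males
  cohort(unclass(base))
}

#' @rdname cohort
#' @param x A `sexed_cohort`.
#' @export
cohort_size <- function(x) sum(x)

#' Allele frequency in a cohort
#'
#' Frequency of the R allele (resistance locus) or the L construct among
#' all copies carried by the cohort, both sexes pooled.
#'
#' @param x A `sexed_cohort`.
#' @param locus `"R"` or `"L"`.
#' @return Proportion in `[0, 1]`, or `NA` for an empty cohort.
#' @export
allele_freq <- function(x, locus = c("R", "L")) {
  locus <- match.arg(locus)
  n <- sum(x)
  if (n == 0) return(NA_real_)
  copies <- if (locus == "R") GENO_R else GENO_L
  sum((x[, "F"] + x[, "M"]) * copies) / (2 * n)
}

#' @export
print.sexed_cohort <- function(x, ...) {
  cat("<sexed_cohort> ", sum(x), " individuals (",
      sum(x[, "F"]), " F / ", sum(x[, "M"]), " M)\n", sep = "")
  nz <- unclass(x)[rowSums(x) > 0, , drop = FALSE]
  if (nrow(nz)) print(nz) else cat("(empty)\n")
  invisible(x)
}
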