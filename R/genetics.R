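# Two-locus genotype machinery: a biallelic Cry1Ac-resistance locus
# (alleles R/S; RR survives high-dose toxin diet, RS/SS do not when
# resistance is recessive) and the insertion site of a dominant,
# tetracycline-repressible, female-specific lethal self-limiting construct
# (alleles L/w). Loci are autosomal and unlinked.

# Fixed enumeration of the nine genotypes: index g = 3*r + l + 1.
GENO_R <- rep(0:2, each = 3)
GENO_L <- rep.int(0:2, 3)
GENO_LABELS <- paste0(c("SS", "RS", "RR")[GENO_R + 1L],
                      c("ww", "Lw", "LL")[GENO_L + 1L])
N_GENO <- 9L
GAMETE_LABELS <- c("S.w", "S.L", "R.w", "R.L")

#' Genotype index
#'
#' Genotypes are identified by the copy number of the resistance allele R
#' (0 = SS, 1 = RS, 2 = RR) and of the self-limiting construct L
#' (0 = ww, 1 = Lw, 2 = LL), and stored as an integer index 1..9 in a fixed
#' enumeration (`genotype_table()` lists it). Released transgenic males are
#' genotype LLSS, i.e. `genotype(0, 2)`.
#'
#' @param r_copies Integer copies of the R allele, each in 0:2.
#' @param l_copies Integer copies of the L construct, each in 0:2.
#' @return Integer genotype index (vectorised).
#' @examples
#' genotype(0, 2)              # the released-male genotype LLSS
#' genotype_label(genotype(2, 0))
#' @export
genotype <- function(r_copies, l_copies) {
  stopifnot(all(r_copies %in% 0:2), all(l_copies %in% 0:2))
  as.integer(3L * r_copies + l_copies + 1L)
}

#' @rdname genotype
#' @param g Integer genotype index in 1..9.
#' @export
genotype_r <- function(g) GENO_R[g]

#' @rdname genotype
#' @export
genotype_l <- function(g) GENO_L[g]

#' @rdname genotype
#' @export
genotype_label <- function(g) GENO_LABELS[g]

#' @rdname genotype
#' @export
genotype_table <- function() {
  data.frame(index = seq_len(N_GENO), r_copies = GENO_R, l_copies = GENO_L,
             label = GENO_LABELS)
}

#' Selection parameters
#'
#' Viability parameters for the two mortality sources: the diagnostic-dose
#' Cry1Ac toxin diet and the female-lethal transgene. The toxin dose used
#' throughout (0.5 ug/ml, carried as a config label) is high enough that
#' resistance is near-recessive, so heterozygote survival `h` defaults to 0;
#' it is a parameter because near-recessive is not strictly recessive.
#'
#' @param h Heterozygote (RS) survival probability on toxin diet.
#' @param toxin_survival Length-3 vector of survival probabilities on toxin
#'   diet for r = 0, 1, 2 copies of R. Defaults to `c(0, h, 1)`: the strict
#'   high-dose case when `h = 0`.
#' @param refuge_survival Baseline egg-to-pupa survival on toxin-free
#'   (refuge) diet, shared by all genotypes.
#' @param fitness_cost_r Multiplicative viability cost per R allele on
#'   refuge diet; 0 by default (costs of resistance are minor in this
#'   system and unquantified).
#' @param tetracycline Logical; when `TRUE` the female-lethal construct is
#'   repressed (as in transgenic stock rearing). Cage populations are reared
#'   off tetracycline, so the default is `FALSE`.
#' @return An object of class `selection_params`.
#' @export
selection_params <- function(h = 0, toxin_survival = c(0, h, 1),
                             refuge_survival = 0.8, fitness_cost_r = 0,
                             tetracycline = FALSE) {
  stopifnot(length(toxin_survival) == 3,
            all(toxin_survival >= 0 & toxin_survival <= 1),
            refuge_survival >= 0, refuge_survival <= 1,
            fitness_cost_r >= 0, fitness_cost_r <= 1,
            is.logical(tetracycline), length(tetracycline) == 1)
  structure(list(toxin_survival = as.numeric(toxin_survival),
                 refuge_survival = as.numeric(refuge_survival),
                 fitness_cost_r = as.numeric(fitness_cost_r),
                 tetracycline = tetracycline,
                 dose_ug_ml = 0.5),
            class = "selection_params")
}

#' Gamete distribution of a genotype
#'
#' Mendelian transmission at two unlinked loci: each gamete carries R with
#' probability `r_copies/2` and L with probability `l_copies/2`,
#' independently (free recombination).
#'
#' @param g Genotype index (see [genotype()]).
#' @return Named numeric vector of length 4 over gamete types
#'   `("S.w", "S.L", "R.w", "R.L")`; sums to 1.
#' @export
gamete_distribution <- function(g) {
  stopifnot(length(g) == 1, g %in% seq_len(N_GENO))
  p_r <- GENO_R[g] / 2
  p_l <- GENO_L[g] / 2
  out <- c((1 - p_r) * (1 - p_l), (1 - p_r) * p_l,
           p_r * (1 - p_l), p_r * p_l)
  names(out) <- GAMETE_LABELS
  out
}

# Per-locus transmission: distribution of offspring copy number given
# parental copy numbers (convolution of two Bernoulli(copies/2) draws).
.locus_offspring <- function(mother_copies, father_copies) {
  pm <- mother_copies / 2
  pf <- father_copies / 2
  c((1 - pm) * (1 - pf), pm * (1 - pf) + (1 - pm) * pf, pm * pf)
}

#' Offspring genotype distribution of a cross
#'
#' Convolution of the parents' gamete distributions; the two loci segregate
#' independently, so the offspring distribution is the outer product of the
#' single-locus transmission distributions.
#'
#' @param mother,father Genotype indices (see [genotype()]).
#' @return Named numeric vector of length 9 over genotype labels; sums to 1.
#' @export
offspring_distribution <- function(mother, father) {
  stopifnot(mother %in% seq_len(N_GENO), father %in% seq_len(N_GENO))
  pr <- .locus_offspring(GENO_R[mother], GENO_R[father])
  pl <- .locus_offspring(GENO_L[mother], GENO_L[father])
  out <- pr[GENO_R + 1L] * pl[GENO_L + 1L]
  names(out) <- GENO_LABELS
  out
}

# Precomputed cross table: OFFSPRING[, i, j] is the offspring genotype
# distribution of mother genotype i crossed with father genotype j.
OFFSPRING <- local({
  arr <- array(0, dim = c(N_GENO, N_GENO, N_GENO),
               dimnames = list(offspring = GENO_LABELS,
                               mother = GENO_LABELS, father = GENO_LABELS))
  for (i in seq_len(N_GENO)) for (j in seq_len(N_GENO)) {
    pr <- .locus_offspring(GENO_R[i], GENO_R[j])
    pl <- .locus_offspring(GENO_L[i], GENO_L[j])
    arr[, i, j] <- pr[GENO_R + 1L] * pl[GENO_L + 1L]
  }
  arr
})

#' Female viability under the self-limiting construct
#'
#' The construct is a dominant female-specific lethal that is repressible by
#' tetracycline: off tetracycline, any female carrying at least one L copy
#' dies (at the larval stage); males are unaffected.
#'
#' @param g Genotype index or vector of indices.
#' @param tetracycline Logical; is the repressor provided?
#' @return Logical vector: is a female of this genotype viable?
#' @export
female_is_viable <- function(g, tetracycline = FALSE) {
  stopifnot(all(g %in% seq_len(N_GENO)))
  GENO_L[g] == 0L | tetracycline
}

#' Egg-to-pupa survival probability on a diet
#'
#' On toxin diet survival depends only on R copy number
#' (`toxin_survival[r + 1]`); on refuge diet all genotypes share the
#' baseline survival, discounted multiplicatively per R copy if a fitness
#' cost is configured. Female-lethality is a separate mortality source and
#' is not part of this probability.
#'
#' @param g Genotype index or vector of indices.
#' @param diet `"toxin"` or `"refuge"`.
#' @param params A [selection_params()] object.
#' @return Numeric vector of survival probabilities.
#' @export
diet_survival <- function(g, diet = c("toxin", "refuge"), params) {
  diet <- match.arg(diet)
  stopifnot(all(g %in% seq_len(N_GENO)), inherits(params, "selection_params"))
  if (diet == "toxin") {
    params$toxin_survival[GENO_R[g] + 1L]
  } else {
    params$refuge_survival * (1 - params$fitness_cost_r)^GENO_R[g]
  }
}
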