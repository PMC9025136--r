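## Synthetic F1 pseudo-testcross populations with known crossover rates,
## linkage phases, interference and missingness.  The generator is the
## ground-truth oracle for every downstream estimator: recombination
## fractions and CoC values implied by the gamma-renewal chiasma model have
## closed forms (gamma_model_rf, gamma_model_coc), so recovery can be tested
## without external data.

#' Simulation configuration for a synthetic F1 population
#'
#' Defaults emulate the study design the package targets: 257 progeny of a
#' single outbred cross, 19 chromosomes with the physical sizes of the
#' reference genome used for mapping (394 Mb total), RAD tags roughly every
#' 300 kb each carrying one female-informative (ab x aa) and one
#' male-informative (aa x ab) SNP less than 1 kb apart, per-interval
#' recombination fractions of a few percent, interference strengths
#' `nu_female = 0.559` and `nu_male = 0.611`, and ~7% missing genotypes.
#'
#' @param n_progeny Number of F1 individuals.
#' @param chromosomes Data frame with columns `name`, `length_bp`,
#'   `length_morgan`.  Optional columns `length_morgan_female` /
#'   `length_morgan_male` give each parent its own genetic map length
#'   (heterochiasmy); `length_morgan` is the fallback for both.
#' @param nu_female,nu_male Gamma interference strength per parent (> 0;
#'   1 = no interference).
#' @param tag_spacing_bp Distance between consecutive RAD tag positions.
#' @param intra_tag_offset_bp Distance between the two SNPs of a tag.
#' @param phase `"random"` (independent fair coin per marker per parent) or
#'   `"coupling"` (all alternate alleles on one homolog).
#' @param missing_rate Per-call probability of a missing genotype, in \[0,1\].
#' @param distortion Optional named numeric vector: for each named marker id,
#'   the transmission probability of the informative parent's alternate
#'   allele (0.5 = Mendelian).  Used only to exercise the segregation filter.
#' @param miscall_rate Per-call probability of flipping het/hom (default 0;
#'   robustness testing only).
#' @param seed Integer RNG seed; `simulate_population()` is bit-reproducible
#'   given the seed.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_progeny = 257,
                       chromosomes = default_chromosomes(),
                       nu_female = 0.559,
                       nu_male = 0.611,
                       tag_spacing_bp = 3e5,
                       intra_tag_offset_bp = 400,
                       phase = c("random", "coupling"),
                       missing_rate = 0.07,
                       distortion = NULL,
                       miscall_rate = 0,
                       seed = 1L) {
  phase <- match.arg(phase)
  stopifnot(
    is.numeric(n_progeny), length(n_progeny) == 1L, n_progeny >= 1,
    is.data.frame(chromosomes),
    all(c("name", "length_bp", "length_morgan") %in% names(chromosomes)),
    nrow(chromosomes) >= 1L,
    all(chromosomes$length_bp > 0), all(chromosomes$length_morgan > 0),
    is.numeric(nu_female), nu_female > 0,
    is.numeric(nu_male), nu_male > 0,
    is.numeric(tag_spacing_bp), tag_spacing_bp > 0,
    is.numeric(intra_tag_offset_bp), intra_tag_offset_bp > 0,
    intra_tag_offset_bp < tag_spacing_bp,
    is.numeric(missing_rate), missing_rate >= 0, missing_rate <= 1,
    is.numeric(miscall_rate), miscall_rate >= 0, miscall_rate <= 1
  )
  if (!is.null(distortion)) {
    stopifnot(is.numeric(distortion), !is.null(names(distortion)),
              all(distortion >= 0 & distortion <= 1))
  }
  structure(
    list(n_progeny = as.integer(n_progeny), chromosomes = chromosomes,
         nu_female = nu_female, nu_male = nu_male,
         tag_spacing_bp = tag_spacing_bp,
         intra_tag_offset_bp = intra_tag_offset_bp, phase = phase,
         missing_rate = missing_rate, distortion = distortion,
         miscall_rate = miscall_rate,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_config")
}

#' Chromosome table mirroring the target genome
#'
#' 19 chromosomes with the physical sizes (Mb) of the paternal reference
#' genome assembly; genetic lengths use a uniform 0.15 Morgan/Mb, which
#' reproduces per-interval recombination fractions around 0.04-0.05 for
#' 300-kb tag intervals.
#'
#' @return Data frame with `name`, `length_bp`, `length_morgan`.
#' @export
default_chromosomes <- function() {
  mb <- c(50.84, 25.34, 20.97, 23.53, 25.39, 27.31, 15.71, 19.71, 13.60,
          22.25, 18.70, 15.30, 15.80, 19.76, 15.07, 14.66, 15.92, 14.60,
          19.64)
  data.frame(name = sprintf("Chr%02d", seq_along(mb)),
             length_bp = mb * 1e6,
             length_morgan = mb * 0.15)
}

#' Chromosome table with a calibrated female/male rate ratio
#'
#' Builds a chromosome table whose per-parent genetic lengths are calibrated
#' so that the model-implied per-interval recombination fraction of the
#' female is `rate_ratio` times the male's at the tag spacing.  Because the
#' recombination fraction over an interval depends on the interference
#' strength (through the equilibrium chiasma distribution), the female map
#' length is solved numerically per chromosome rather than scaled linearly.
#'
#' @param n_chrom Number of chromosomes.
#' @param length_bp Physical length per chromosome (recycled).
#' @param male_morgan Male genetic length per chromosome (recycled).
#' @param rate_ratio Target female/male per-interval rate ratio.
#' @param nu_female,nu_male Interference strengths used in the calibration.
#' @param tag_spacing_bp Tag spacing at which the ratio is imposed.
#' @return Chromosome data frame for [sim_config()] with per-parent
#'   genetic lengths.
#' @export
heterochiasmy_chromosomes <- function(n_chrom = 5, length_bp = 2e7,
                                      male_morgan = 3, rate_ratio = 1.3,
                                      nu_female = 0.55, nu_male = 0.9,
                                      tag_spacing_bp = 3e5) {
  length_bp <- rep_len(length_bp, n_chrom)
  male_morgan <- rep_len(male_morgan, n_chrom)
  lm_f <- vapply(seq_len(n_chrom), function(i) {
    d_m <- tag_spacing_bp / length_bp[i] * male_morgan[i]
    target <- rate_ratio * gamma_model_rf(d_m, nu_male)
    if (target >= 0.5) stop("target rate ratio unattainable (r >= 0.5)")
    d_f <- stats::uniroot(function(d) gamma_model_rf(d, nu_female) - target,
                          lower = 1e-8, upper = 10, tol = 1e-10)$root
    d_f * length_bp[i] / tag_spacing_bp
  }, numeric(1))
  data.frame(name = sprintf("Chr%02d", seq_len(n_chrom)),
             length_bp = length_bp,
             length_morgan = male_morgan,
             length_morgan_female = lm_f,
             length_morgan_male = male_morgan)
}

#' Construct a genotype dataset object
#'
#' @param markers Data frame with columns `chrom`, `pos` (bp, 1-based), `id`,
#'   `seg_type` (one of `"AB_X_AA"`, `"AA_X_AB"`, `"other"`).
#' @param calls Integer matrix, markers x individuals: 1 = het, 0 = hom,
#'   `NA` = missing.  Het/hom is coded relative to the informative parent:
#'   hom means the progeny equals the homozygous parent's genotype.
#' @param chrom_sizes Optional data frame `chrom`, `length_bp`.
#' @return Object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(markers, calls, chrom_sizes = NULL) {
  stopifnot(is.data.frame(markers),
            all(c("chrom", "pos", "id", "seg_type") %in% names(markers)),
            is.matrix(calls), nrow(calls) == nrow(markers),
            all(markers$pos >= 1),
            all(markers$seg_type %in% c("AB_X_AA", "AA_X_AB", "other")))
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("ind%03d", seq_len(ncol(calls)))
  rownames(calls) <- markers$id
  structure(list(markers = markers, calls = calls,
                 chrom_sizes = chrom_sizes),
            class = "genotype_dataset")
}

#' @exportS3Method base::print
print.genotype_dataset <- function(x, ...) {
  tab <- table(x$markers$seg_type)
  cat(sprintf(
    "genotype_dataset: %d SNPs x %d individuals on %d chromosome(s)\n",
    nrow(x$markers), ncol(x$calls), length(unique(x$markers$chrom))))
  cat("  segregation types:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  missing calls: %.1f%%\n", 100 * mean(is.na(x$calls))))
  invisible(x)
}

## linear physical <-> genetic map for one chromosome
bp_to_morgan <- function(bp, length_bp, length_morgan) {
  bp / length_bp * length_morgan
}

#' Simulate an F1 pseudo-testcross population
#'
#' For every progeny, chromosome and parent, one transmitted chromatid is
#' drawn from the thinned stationary gamma-renewal crossover model
#' ([simulate_chromatid_crossovers()]).  The genotype at a marker informative
#' for that parent is het if the transmitted allele is the informative
#' parent's alternate allele, hom otherwise; linkage phases assign the
#' alternate allele to a homolog per marker.  Missingness (and optionally
#' transmission distortion and miscalls) are applied afterwards.
#'
#' @param config A [sim_config()] object.
#' @return A list with components
#'   \describe{
#'     \item{dataset}{[genotype_dataset()] of all simulated SNPs.}
#'     \item{truth}{Ground truth: `intervals` (per-parent adjacent-marker
#'       intervals with model-implied recombination fraction `r_true`),
#'       `coc` (model-implied CoC for adjacent interval pairs), `nu`
#'       (true strengths), `crossovers` (per-meiosis CO positions in
#'       Morgans and bp), `phases` (per-marker homolog assignment).}
#'   }
#' @export
simulate_population <- function(config) {
  if (!inherits(config, "sim_config")) stop("`config` must be a sim_config")
  if (config$n_progeny < 1L) stop("config has zero progeny")
  if (!is.null(config$seed)) set.seed(config$seed)

  chroms <- config$chromosomes
  n <- config$n_progeny
  progeny <- sprintf("F1_%03d", seq_len(n))
  nu <- c(female = config$nu_female, male = config$nu_male)

  marker_list <- list()
  call_list <- list()
  truth_int <- list()
  truth_coc <- list()
  truth_xo <- list()
  truth_phase <- list()

  for (ci in seq_len(nrow(chroms))) {
    chrom <- chroms$name[ci]
    Lbp <- chroms$length_bp[ci]
    Lm_parent <- c(
      female = if ("length_morgan_female" %in% names(chroms))
        chroms$length_morgan_female[ci] else chroms$length_morgan[ci],
      male = if ("length_morgan_male" %in% names(chroms))
        chroms$length_morgan_male[ci] else chroms$length_morgan[ci])
    tag_pos <- seq(config$tag_spacing_bp, Lbp - config$intra_tag_offset_bp,
                   by = config$tag_spacing_bp)
    if (length(tag_pos) < 1L) stop("chromosome too short for any marker")
    pos_f <- tag_pos
    pos_m <- tag_pos + config$intra_tag_offset_bp
    mk <- data.frame(
      chrom = chrom,
      pos = as.integer(c(rbind(pos_f, pos_m))),
      id = sprintf("%s_T%03d_%s", chrom,
                   rep(seq_along(tag_pos), each = 2), c("f", "m")),
      seg_type = rep(c("AB_X_AA", "AA_X_AB"), times = length(tag_pos)))
    marker_list[[ci]] <- mk

    calls <- matrix(NA_integer_, nrow(mk), n,
                    dimnames = list(mk$id, progeny))
    for (parent in c("female", "male")) {
      Lm <- Lm_parent[[parent]]
      sel <- mk$seg_type == if (parent == "female") "AB_X_AA" else "AA_X_AB"
      gpos <- bp_to_morgan(mk$pos[sel], Lbp, Lm)
      phase <- if (config$phase == "coupling") integer(sum(sel))
               else stats::rbinom(sum(sel), 1L, 0.5)
      truth_phase[[length(truth_phase) + 1L]] <- data.frame(
        id = mk$id[sel], parent = parent, phase = phase)
      for (i in seq_len(n)) {
        xo <- simulate_chromatid_crossovers(Lm, nu[[parent]])
        if (length(xo))
          truth_xo[[length(truth_xo) + 1L]] <- data.frame(
            progeny = progeny[i], parent = parent, chrom = chrom,
            pos_morgan = xo, pos_bp = xo / Lm * Lbp)
        parity <- findInterval(gpos, xo) %% 2L
        hap <- (stats::rbinom(1L, 1L, 0.5) + parity) %% 2L
        calls[sel, i] <- as.integer(hap == phase)
      }
      ## model-implied truth on adjacent informative-marker intervals
      if (sum(sel) >= 2L) {
        d <- diff(gpos)
        truth_int[[length(truth_int) + 1L]] <- data.frame(
          parent = parent, chrom = chrom,
          left_pos = mk$pos[sel][-sum(sel)], right_pos = mk$pos[sel][-1L],
          d_morgan = d, r_true = gamma_model_rf(d, nu[[parent]]))
        if (sum(sel) >= 3L) {
          d1 <- d[-length(d)]; d2 <- d[-1L]
          truth_coc[[length(truth_coc) + 1L]] <- data.frame(
            parent = parent, chrom = chrom,
            pos1 = mk$pos[sel][seq_len(sum(sel) - 2L)],
            pos2 = mk$pos[sel][seq_len(sum(sel) - 2L) + 1L],
            pos3 = mk$pos[sel][seq_len(sum(sel) - 2L) + 2L],
            coc_true = gamma_model_coc(d1, d2, nu[[parent]]))
        }
      }
    }
    call_list[[ci]] <- calls
  }

  markers <- do.call(rbind, marker_list)
  calls <- do.call(rbind, call_list)

  ## optional transmission distortion: overrides linked calls at named SNPs
  if (!is.null(config$distortion)) {
    for (id in names(config$distortion)) {
      j <- match(id, markers$id)
      if (is.na(j)) next
      calls[j, ] <- stats::rbinom(n, 1L, config$distortion[[id]])
    }
  }
  if (config$miscall_rate > 0) {
    flip <- matrix(stats::runif(length(calls)) < config$miscall_rate,
                   nrow(calls))
    calls[flip] <- 1L - calls[flip]
  }
  if (config$missing_rate > 0) {
    calls[matrix(stats::runif(length(calls)) < config$missing_rate,
                 nrow(calls))] <- NA_integer_
  }

  dataset <- genotype_dataset(
    markers, calls,
    chrom_sizes = data.frame(chrom = chroms$name,
                             length_bp = chroms$length_bp))
  truth <- list(
    intervals = do.call(rbind, truth_int),
    coc = if (length(truth_coc)) do.call(rbind, truth_coc) else NULL,
    nu = nu,
    crossovers = if (length(truth_xo)) do.call(rbind, truth_xo) else NULL,
    phases = do.call(rbind, truth_phase),
    config = config)
  list(dataset = dataset, truth = truth)
}

## canonical class probabilities ------------------------------------------

## two-point classes ordered (het,het), (het,hom), (hom,het), (hom,hom)
two_point_probs <- function(r, phase = c("coupling", "repulsion")) {
  phase <- match.arg(phase)
  stopifnot(r >= 0, r <= 0.5)
  p <- c((1 - r) / 2, r / 2, r / 2, (1 - r) / 2)
  if (phase == "repulsion") p <- p[c(2L, 1L, 4L, 3L)]
  p
}

## three-point classes in lexicographic order with het before hom:
## 1=(H,H,H) ... 8=(O,O,O).  `phases` gives the linkage phase of the two
## sub-pairs (marker1-2, marker2-3).
three_point_probs <- function(r1, r2, coc,
                              phases = c("coupling", "coupling")) {
  stopifnot(r1 >= 0, r1 <= 0.5, r2 >= 0, r2 <= 0.5, coc >= 0,
            length(phases) == 2L,
            all(phases %in% c("coupling", "repulsion")))
  p11 <- r1 * r2 * coc
  p01 <- r2 - p11
  p10 <- r1 - p11
  p00 <- 1 - r1 - r2 + p11
  if (min(p00, p01, p10, p11) < -1e-12)
    stop("invalid (r1, r2, CoC): some class frequency is negative")
  base <- pmax(c(p00, p01, p11, p10, p10, p11, p01, p00) / 2, 0)
  ## homolog assignment implied by the sub-pair phases (marker 1 fixed)
  f2 <- as.integer(phases[1L] == "repulsion")
  f3 <- xor(f2, phases[2L] == "repulsion")
  flip <- c(0L, f2, as.integer(f3))
  if (all(flip == 0L)) return(base)
  idx <- vapply(0:7, function(b) {
    bits <- c(b %/% 4L, (b %/% 2L) %% 2L, b %% 2L)
    sum(bitwXor(bits, flip) * c(4L, 2L, 1L)) + 1L
  }, integer(1))
  base[idx]
}

#' Simulate a multinomial genotype-class count table
#'
#' Draws counts from the exact genotype-class probabilities of the two-point
#' (four classes) or three-point (eight classes) pseudo-testcross model,
#' for unit-testing the estimators against known parameters.
#'
#' @param n Number of progeny (multinomial size).
#' @param r Two-point recombination fraction in \[0, 0.5\] (two-point mode).
#' @param r1,r2 Adjacent-interval CO rates (three-point mode).
#' @param coc Coefficient of coincidence `C >= 0`; all implied class
#'   frequencies must lie in \[0, 1\].
#' @param phase Two-point: `"coupling"` or `"repulsion"`.  Three-point: a
#'   length-2 vector with the phases of the two sub-pairs.
#' @return Integer count vector of length 4 or 8 summing to `n`, classes in
#'   canonical order (het before hom, leftmost marker most significant).
#' @examples
#' set.seed(1)
#' simulate_count_table(100, r = 0.05)
#' simulate_count_table(1000, r1 = 0.2, r2 = 0.1, coc = 1)
#' @export
simulate_count_table <- function(n, r = NULL, r1 = NULL, r2 = NULL,
                                 coc = NULL, phase = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n > 0)
  if (!is.null(r)) {
    p <- two_point_probs(r, if (is.null(phase)) "coupling" else phase)
  } else if (!is.null(r1) && !is.null(r2) && !is.null(coc)) {
    p <- three_point_probs(
      r1, r2, coc,
      if (is.null(phase)) c("coupling", "coupling") else phase)
  } else {
    stop("supply either `r` (two-point) or `r1`, `r2`, `coc` (three-point)")
  }
  as.integer(stats::rmultinom(1L, n, p))
}
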