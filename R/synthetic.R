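# Seeded generator of synthetic coding sequences with controllable group
# GC3, within-family codon bias and mutation-versus-selection regimes.
# Amino acids are drawn from a configurable usage vector; within each
# synonymous family the codon choice is exponentially tilted on
# third-position G+C, with the tilt solved per sequence so the expected
# GC3 hits the target. Codon counts per amino acid are filled by
# randomised rounding of the expected counts, which keeps realised GC3
# tightly around its expectation.

# per-amino-acid GC fraction averaged over codon positions 1 and 2 under
# uniform within-family usage; the lever through which amino-acid
# composition moves GC12
AA_GC12 <- local({
  vapply(SYN_FAMILIES, function(fam) {
    b1 <- substr(fam, 1L, 1L)
    b2 <- substr(fam, 2L, 2L)
    (mean(b1 %in% c("G", "C")) + mean(b2 %in% c("G", "C"))) / 2
  }, numeric(1))
})

# third-position G+C indicator per codon, by family
AA_GC3 <- lapply(SYN_FAMILIES, function(fam) {
  as.numeric(substr(fam, 3L, 3L) %in% c("G", "C"))
})

#' Default amino-acid usage weights
#'
#' A usage vector enriched in leucine, glutamine and serine, the profile
#' typical of forkhead-box transcription factors such as FoxP2 (which
#' carries a long polyglutamine tract).
#'
#' @return Named numeric vector over the 20 amino acids, summing to 1.
#' @export
default_aa_weights <- function() {
  w <- c(A = 0.055, R = 0.045, N = 0.040, D = 0.052, C = 0.015,
         Q = 0.120, E = 0.050, G = 0.050, H = 0.025, I = 0.040,
         L = 0.110, K = 0.045, M = 0.020, F = 0.030, P = 0.060,
         S = 0.100, T = 0.050, W = 0.008, V = 0.055, Y = 0.030)
  w <- w[AMINO_ACIDS]
  w / sum(w)
}

# within-family codon weights: deterministic preference for the family's
# first codon (strength = bias) times the exponential GC3 tilt (beta)
family_codon_prob <- function(aa, beta, bias) {
  fam <- SYN_FAMILIES[[aa]]
  k <- length(fam)
  if (k == 1L) return(1)
  w <- exp(bias * c(1, rep(0, k - 1L)) + beta * AA_GC3[[aa]])
  w / sum(w)
}

# expected third-position GC for one amino acid at tilt beta
family_gc3_expectation <- function(aa, beta, bias) {
  sum(family_codon_prob(aa, beta, bias) * AA_GC3[[aa]])
}

# solve the GC3 tilt so that the expected GC3 over the realised
# amino-acid counts equals the target s
solve_beta <- function(n_aa, s, bias) {
  L <- sum(n_aa)
  f <- function(beta) {
    q <- vapply(AMINO_ACIDS, family_gc3_expectation, numeric(1),
                beta = beta, bias = bias)
    sum(n_aa * q) / L - s
  }
  lo <- -40; hi <- 40
  if (f(lo) > 0 || f(hi) < 0) {
    stop("gc3_target ", signif(s, 3), " infeasible for this amino-acid ",
         "composition (attainable range ",
         signif(f(lo) + s, 3), "-", signif(f(hi) + s, 3), ")")
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

# mutation regime: tilt the amino-acid weights so the expected GC12
# matches the target; p12(gamma) is monotone in gamma
tilt_aa_weights <- function(w, target_p12) {
  p12_at <- function(gamma) {
    wg <- w * exp(gamma * AA_GC12)
    wg <- wg / sum(wg)
    sum(wg * AA_GC12)
  }
  lo <- -12; hi <- 12
  target <- min(max(target_p12, p12_at(lo) + 1e-3), p12_at(hi) - 1e-3)
  gamma <- stats::uniroot(function(g) p12_at(g) - target,
                          c(lo, hi), tol = 1e-10)$root
  wg <- w * exp(gamma * AA_GC12)
  wg / sum(wg)
}

#' Configuration for the synthetic CDS generator
#'
#' @param n_sequences Number of sequences (>= 1).
#' @param length_codons Mean number of sense codons per sequence
#'   (default 710, i.e. a CDS of about 2,130 nt).
#' @param length_sd Standard deviation of the per-sequence codon count
#'   (default 0: fixed length).
#' @param gc3_target Target third-position G+C. Either a single value in
#'   (0, 1) or a length-2 range; per-sequence targets are drawn uniformly
#'   from `gc3_target +/- gc3_halfwidth` (or from the range). `NA`
#'   disables GC3 steering entirely (tilt fixed at 0), leaving codon
#'   choice to `bias_strength` alone.
#' @param gc3_halfwidth Half-width of the per-sequence GC3 spread
#'   (default 0.12; ignored when `gc3_target` is a range).
#' @param regime `"selection"` (amino-acid usage held fixed, so GC12 stays
#'   flat while GC3 varies) or `"mutation"` (amino-acid usage co-varies
#'   with the per-sequence GC3 target, so GC12 tracks GC3).
#' @param bias_strength Non-negative concentration of within-family codon
#'   choice on one deterministic preferred codon per family; 0 = uniform
#'   within family, large values collapse each family to a single codon.
#' @param aa_weights Amino-acid usage probabilities (named 20-vector,
#'   normalised internally). Default [default_aa_weights()].
#' @param group_label Group label attached to all generated sequences.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_sequences, length_codons = 710L,
                             length_sd = 0, gc3_target = 0.5,
                             gc3_halfwidth = 0.12,
                             regime = c("selection", "mutation"),
                             bias_strength = 0,
                             aa_weights = default_aa_weights(),
                             group_label = "synthetic", seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(n_sequences >= 1L, length_codons >= 10L, length_sd >= 0,
            bias_strength >= 0, gc3_halfwidth >= 0)
  if (length(gc3_target) == 2L) {
    rng <- sort(gc3_target)
    gc3_target <- mean(rng)
    gc3_halfwidth <- diff(rng) / 2
  }
  stopifnot(length(gc3_target) == 1L)
  if (is.na(gc3_target)) {
    if (regime == "mutation") {
      stop("the mutation regime needs a numeric gc3_target")
    }
  } else {
    stopifnot(gc3_target > 0, gc3_target < 1)
  }
  if (is.null(names(aa_weights)) || !setequal(names(aa_weights), AMINO_ACIDS)) {
    stop("aa_weights must be named by the 20 one-letter amino acids")
  }
  if (any(aa_weights < 0) || sum(aa_weights) <= 0) {
    stop("aa_weights must be non-negative with positive sum")
  }
  aa_weights <- aa_weights[AMINO_ACIDS] / sum(aa_weights)
  structure(list(n_sequences = as.integer(n_sequences),
                 length_codons = as.integer(length_codons),
                 length_sd = length_sd, gc3_target = gc3_target,
                 gc3_halfwidth = gc3_halfwidth, regime = regime,
                 bias_strength = bias_strength, aa_weights = aa_weights,
                 group_label = group_label, seed = as.integer(seed)),
            class = "generator_config")
}

# randomised rounding of expected codon counts: floor the expectations,
# then distribute the remainder with probability proportional to the
# fractional parts; keeps realised GC3 within O(1/L) of its expectation
quota_counts <- function(n, prob) {
  expected <- prob * n
  base <- floor(expected)
  rem <- n - sum(base)
  if (rem > 0L) {
    frac <- expected - base
    extra <- sample.int(length(prob), rem, replace = FALSE,
                        prob = frac + 1e-12)
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

.gen_sequence <- function(cfg, idx) {
  L <- max(50L, as.integer(round(stats::rnorm(1, cfg$length_codons,
                                              cfg$length_sd))))
  steer <- !is.na(cfg$gc3_target)
  if (steer) {
    s <- stats::runif(1, cfg$gc3_target - cfg$gc3_halfwidth,
                      cfg$gc3_target + cfg$gc3_halfwidth)
    s <- min(max(s, 0.02), 0.98)
  }
  w <- cfg$aa_weights
  if (cfg$regime == "mutation") w <- tilt_aa_weights(w, target_p12 = s)
  aa <- c("M", sample(AMINO_ACIDS, L - 1L, replace = TRUE, prob = w))
  n_aa <- table(factor(aa, levels = AMINO_ACIDS))
  if (steer) {
    s_min <- (n_aa[["M"]] + n_aa[["W"]]) / L
    if (s <= s_min + 0.005) {
      stop("gc3_target ", signif(s, 3), " infeasible: Met/Trp codons force ",
           "a minimum GC3 of ", signif(s_min, 3))
    }
  }
  beta <- if (steer) solve_beta(n_aa, s, cfg$bias_strength) else 0
  codons <- character(L)
  for (a in AMINO_ACIDS) {
    n <- n_aa[[a]]
    if (n == 0L) next
    fam <- SYN_FAMILIES[[a]]
    if (length(fam) == 1L) {
      codons[aa == a] <- fam
      next
    }
    cnt <- quota_counts(n, family_codon_prob(a, beta, cfg$bias_strength))
    codons[aa == a] <- sample(rep(fam, cnt))
  }
  paste0(paste(codons, collapse = ""), sample(STOP_CODONS, 1L))
}

.generate_dataset <- function(cfg) {
  seqs <- vector("list", cfg$n_sequences)
  for (i in seq_len(cfg$n_sequences)) {
    id <- sprintf("%s_%03d", cfg$group_label, i)
    res <- validate_cds(id, .gen_sequence(cfg, i), cfg$group_label)
    if (inherits(res, "cds_rejection")) {
      stop("internal error: generated sequence rejected (", res$reason, ")")
    }
    seqs[[i]] <- res
  }
  ds <- new_grouped_dataset(seqs, NULL)
  attr(ds, "seed") <- cfg$seed
  ds
}

#' Generate a synthetic CDS dataset
#'
#' Draws `n_sequences` coding sequences under a [generator_config()].
#' Every sequence starts with ATG, ends with a single stop codon and
#' contains no internal stops or ambiguous bases, so all of them pass
#' [validate_cds()] by construction. With a fixed seed the output is
#' byte-identical across runs.
#'
#' @param config A `generator_config`.
#' @return A `grouped_dataset` with the seed recorded in
#'   `attr(, "seed")`.
#' @export
#' @examples
#' ds <- generate_dataset(generator_config(3, length_codons = 200, seed = 7))
#' length(ds$sequences)
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  .generate_dataset(config)
}

#' Generate the four-group taxon-like panel
#'
#' A labelled dataset emulating the group structure of a vertebrate
#' FoxP2-style study: a GC3-high fish-like group (target 0.632) and
#' bird- (0.453), reptile- (0.434) and mammal-like (0.490) groups, with
#' group-specific CDS lengths around 2,100-2,250 nt. All groups use the
#' selection regime (amino-acid usage fixed) with per-group GC3 spreads
#' matching the targets' dispersion.
#'
#' @param n_per_group Sequences per group (>= 3; default 20).
#' @param seed Integer seed.
#' @return A `grouped_dataset` with groups `fish`, `bird`, `reptile`,
#'   `mammal`.
#' @export
generate_regime_panel <- function(n_per_group = 20L, seed = 1L) {
  stopifnot(n_per_group >= 3L)
  specs <- list(
    fish    = list(length = 742L, length_sd = 33.9, gc3 = 0.632, hw = 0.090),
    bird    = list(length = 705L, length_sd =  9.4, gc3 = 0.453, hw = 0.009),
    reptile = list(length = 717L, length_sd = 14.1, gc3 = 0.434, hw = 0.021),
    mammal  = list(length = 710L, length_sd = 12.2, gc3 = 0.490, hw = 0.049))
  set.seed(seed)
  seqs <- list()
  for (g in names(specs)) {
    sp <- specs[[g]]
    cfg <- generator_config(n_per_group, length_codons = sp$length,
                            length_sd = sp$length_sd, gc3_target = sp$gc3,
                            gc3_halfwidth = sp$hw, regime = "selection",
                            group_label = g, seed = seed)
    ds <- .generate_dataset(cfg)
    seqs <- c(seqs, ds$sequences)
  }
  panel <- new_grouped_dataset(seqs, NULL)
  attr(panel, "seed") <- as.integer(seed)
  panel
}
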