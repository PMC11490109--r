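#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults are the
#' desk-scale study conditions used throughout the package: 4 populations
#' of 200 haplotypes, a 5-Mb chromosome with 5,000 sites, per-site mutation
#' rate 2.5e-3 per generation (chosen so 2N*mu = 1, which holds site
#' frequencies near the uniform stationary distribution at this small N),
#' recombination 1e-8 per bp per generation, and a Wright-Fisher burn-in of
#' 8N generations.
#'
#' @param n_populations Number of populations (breeds).
#' @param haplotypes_per_population Haplotypes per population (= WF
#'   population size; diploid sample size is half).
#' @param n_sites Number of variant sites on the chromosome.
#' @param chrom_length_bp Chromosome length in bp.
#' @param mutation_rate Per-site per-generation 0<->1 flip probability.
#' @param recombination_rate Per-bp per-generation crossover rate.
#' @param wf_generations Burn-in generations; `NULL` means `8 * N` when
#'   `balding_nichols_F == 0` and `0` in Balding-Nichols mode (divergence
#'   is then carried entirely by the beta-sampled founder frequencies).
#' @param balding_nichols_F Target differentiation in `[0, 1)`; when > 0,
#'   per-population site frequencies are drawn around a shared ancestral
#'   frequency via the Balding-Nichols beta model and founders are sampled
#'   i.i.d. from them.
#' @param sweep_specs List of `list(population, core_pos_bp,
#'   target_derived_freq)` incomplete-sweep injections.
#' @param eqtl_spec List with `n_eqtl`, `planted_spearman_rho`,
#'   `slope_scale`.
#' @param expression_spec List of arguments for [simulate_expression()].
#' @param chrom Chromosome label.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_populations = 4, haplotypes_per_population = 200,
                       n_sites = 5000, chrom_length_bp = 5e6,
                       mutation_rate = 2.5e-3, recombination_rate = 1e-8,
                       wf_generations = NULL, balding_nichols_F = 0,
                       sweep_specs = list(), eqtl_spec = NULL,
                       expression_spec = NULL, chrom = "1", seed = 1L) {
  stopifnot(n_populations >= 1, haplotypes_per_population >= 4,
            haplotypes_per_population %% 2 == 0, n_sites >= 2,
            chrom_length_bp > n_sites, mutation_rate >= 0,
            recombination_rate >= 0)
  if (balding_nichols_F < 0 || balding_nichols_F >= 1) {
    stop("balding_nichols_F must be in [0, 1)")
  }
  for (sw in sweep_specs) {
    if (sw$target_derived_freq <= 0 || sw$target_derived_freq >= 1) {
      stop("sweep target_derived_freq must be in (0, 1)")
    }
  }
  if (!is.null(eqtl_spec) && !is.null(eqtl_spec$planted_spearman_rho) &&
      abs(eqtl_spec$planted_spearman_rho) > 1) {
    stop("planted_spearman_rho must be in [-1, 1]")
  }
  if (is.null(wf_generations)) {
    wf_generations <- if (balding_nichols_F > 0) 0L else
      8L * haplotypes_per_population
  }
  structure(list(
    n_populations = n_populations,
    haplotypes_per_population = haplotypes_per_population,
    n_sites = n_sites, chrom_length_bp = chrom_length_bp,
    mutation_rate = mutation_rate,
    recombination_rate = recombination_rate,
    wf_generations = wf_generations,
    balding_nichols_F = balding_nichols_F,
    sweep_specs = sweep_specs, eqtl_spec = eqtl_spec,
    expression_spec = expression_spec, chrom = chrom,
    seed = as.integer(seed)), class = "sim_config")
}

#' Simulate neutral multi-population haplotypes
#'
#' Forward Wright-Fisher simulation on a fixed site grid with per-site
#' mutation and Poisson crossover, run independently per population after
#' the founders are drawn. With `balding_nichols_F > 0` the founder allele
#' frequencies of each population are beta-distributed around a shared
#' ancestral frequency (Balding-Nichols model), giving a known expected
#' differentiation; with `F == 0` each population starts from the shared
#' frequencies and linkage disequilibrium builds up over the burn-in.
#'
#' @param cfg A [sim_config()].
#' @return Named list of [haplotype_set()], one per population
#'   (`pop1`, `pop2`, ...); the seed is recorded as an attribute.
#' @export
simulate_neutral_haplotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$n_sites
  N <- cfg$haplotypes_per_population
  positions <- sort(sample.int(cfg$chrom_length_bp, L))
  p0 <- stats::runif(L, 0.05, 0.95)
  FF <- cfg$balding_nichols_F
  out <- vector("list", cfg$n_populations)
  names(out) <- sprintf("pop%d", seq_len(cfg$n_populations))
  any_poly <- FALSE
  for (k in seq_len(cfg$n_populations)) {
    pk <- if (FF > 0) {
      stats::rbeta(L, p0 * (1 - FF) / FF, (1 - p0) * (1 - FF) / FF)
    } else p0
    founders <- matrix(stats::rbinom(L * N, 1L, rep(pk, N)),
                       nrow = L, ncol = N) # site-major
    h <- if (cfg$wf_generations > 0) {
      wf_evolve_cpp(founders, cfg$wf_generations, positions,
                    cfg$recombination_rate, cfg$mutation_rate)
    } else founders
    freq <- rowMeans(h)
    if (any(freq > 0 & freq < 1)) any_poly <- TRUE
    out[[k]] <- haplotype_set(cfg$chrom, positions, t(h),
                              population = names(out)[k])
  }
  if (!any_poly) {
    stop("simulated genome is monomorphic in every population; ",
         "increase mutation_rate or founder diversity")
  }
  attr(out, "seed") <- cfg$seed
  attr(out, "config") <- cfg
  out
}

#' Inject an incomplete selective sweep
#'
#' Haplotype-copying construction of a recent incomplete sweep: a donor
#' carrier of the derived allele at the core variant has local segments
#' copied onto randomly chosen non-carriers until the derived frequency at
#' the core reaches (the nearest achievable value to) `target_freq`. Each
#' recipient's copied extent on either side of the core is drawn from an
#' exponential distribution with mean `mean_extent_bp`, mimicking the
#' breakup of a sweeping haplotype by recombination (mean extent inversely
#' proportional to the recombination rate).
#'
#' @param haps A [haplotype_set()].
#' @param core_pos Target core position in bp (nearest polymorphic variant
#'   with a derived allele is used).
#' @param target_freq Target derived allele frequency at the core, in
#'   (0, 1); must not be below the current frequency.
#' @param seed Optional seed.
#' @param mean_extent_bp Mean copied extent per side (default 1e5, i.e.
#'   0.001 / recombination_rate at the default 1e-8; yields the kb-scale
#'   signatures typical of dense sequence-based scans).
#' @param max_shift_bp How far from `core_pos` a suitable core variant
#'   (polymorphic, derived frequency not above `target_freq`) may be
#'   sought (default 100 kb).
#' @return A `haplotype_set` with the sweep injected; the realized core
#'   index/position and carrier set are recorded as attributes.
#' @export
inject_sweep <- function(haps, core_pos, target_freq, seed = NULL,
                         mean_extent_bp = 1e5, max_shift_bp = 1e5) {
  stopifnot(inherits(haps, "haplotype_set"))
  if (target_freq <= 0 || target_freq >= 1) {
    stop("target_freq must be in (0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  h <- haps$haplotypes
  n <- nrow(h)
  freq <- colMeans(h)
  target <- round(target_freq * n)
  usable <- which(freq > 0 & freq < 1 &
                    abs(haps$positions - core_pos) <= max_shift_bp)
  if (!length(usable)) stop("no polymorphic variant available as sweep ",
                            "core within ", max_shift_bp, " bp of ",
                            core_pos)
  cnt <- colSums(h[, usable, drop = FALSE])
  # prefer a low-frequency core (a recent sweep lifts a rare haplotype),
  # falling back to any candidate not already above the target
  low <- usable[cnt <= pmin(target, ceiling(0.25 * n))]
  ok <- if (length(low)) low else usable[cnt <= target]
  if (!length(ok)) {
    nearest <- usable[which.min(abs(haps$positions[usable] - core_pos))]
    stop("target_freq (", target_freq, ") is below the current derived ",
         "frequency (", freq[nearest], ") at every candidate core; ",
         "reverse sweeps are not supported")
  }
  core <- ok[which.min(abs(haps$positions[ok] - core_pos))]
  cur <- sum(h[, core])
  if (target > cur) {
    carriers <- which(h[, core] == 1L)
    donor <- carriers[1L]
    recipients <- sample(which(h[, core] == 0L), target - cur)
    pos <- haps$positions
    for (r in recipients) {
      lo <- pos[core] - stats::rexp(1, rate = 1 / mean_extent_bp)
      hi <- pos[core] + stats::rexp(1, rate = 1 / mean_extent_bp)
      cols <- which(pos >= lo & pos <= hi)
      h[r, cols] <- h[donor, cols]
    }
  }
  out <- haplotype_set(haps$chrom, haps$positions, h,
                       sample_ids = haps$sample_ids,
                       population = haps$population,
                       ancestral_policy = haps$ancestral_policy)
  attr(out, "sweep_core_index") <- core
  attr(out, "sweep_core_pos") <- haps$positions[core]
  out
}

#' Simulate cis-eQTL slopes rank-coupled to FST
#'
#' Generates slopes whose absolute value has a target Spearman correlation
#' with per-variant FST via a Gaussian copula: the normal scores of the FST
#' ranks are mixed with independent noise at the Pearson correlation
#' `2*sin(pi*rho/6)` that induces Spearman `rho` for a bivariate Gaussian,
#' then mapped monotonically to a log-normal magnitude. Signs are random.
#'
#' @param fst A data.frame with columns `chrom`, `pos`, `global_fst` (as
#'   from [wc_fst()]) or a bare numeric vector of FST values.
#' @param rho Target Spearman correlation between FST and `|slope|`,
#'   in `[-1, 1]`.
#' @param seed Optional seed.
#' @param tissue Tissue label for the emitted records.
#' @param slope_scale Log-scale spread of slope magnitudes.
#' @return data.frame of eQTL records (`evariant_id`, `chrom`, `pos`,
#'   `tissue`, `egene`, `slope`).
#' @export
simulate_eqtl_slopes <- function(fst, rho, seed = NULL, tissue = "tissue1",
                                 slope_scale = 0.5) {
  if (abs(rho) > 1) stop("rho must be in [-1, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (is.numeric(fst)) {
    fst <- data.frame(chrom = "1", pos = seq_along(fst), global_fst = fst)
  }
  stopifnot(all(is.finite(fst$global_fst)))
  n <- nrow(fst)
  r <- 2 * sin(pi * rho / 6)
  z1 <- stats::qnorm((rank(fst$global_fst, ties.method = "average") - 0.5) / n)
  z2 <- r * z1 + sqrt(max(0, 1 - r^2)) * stats::rnorm(n)
  magnitude <- exp(slope_scale * z2)
  sign <- sample(c(-1, 1), n, replace = TRUE)
  data.frame(
    evariant_id = sprintf("%s_%d", fst$chrom, as.integer(fst$pos)),
    chrom = fst$chrom, pos = fst$pos, tissue = tissue,
    egene = sprintf("gene%05d", seq_len(n)),
    slope = sign * magnitude, stringsAsFactors = FALSE)
}

#' Simulate a tissue expression matrix with planted overexpressed genes
#'
#' Log-expression = per-gene baseline + `log_fold_change` for planted
#' (gene, tissue) pairs + Gaussian noise.
#'
#' @param n_genes,n_tissues,samples_per_tissue Matrix dimensions.
#' @param overexpressed_sets Named list `tissue -> gene ids` of planted
#'   overexpressed genes; `NULL` plants disjoint sets of
#'   `n_overexpressed_per_tissue` genes per tissue.
#' @param n_overexpressed_per_tissue Planted set size when auto-planting.
#' @param log_fold_change Planted shift, log-expression units.
#' @param noise_sd Gaussian noise SD.
#' @param baseline_mean,baseline_sd Per-gene baseline distribution.
#' @param seed Optional seed.
#' @return An [expression_matrix()]; the planted sets are in
#'   `attr(, "ground_truth")`.
#' @export
simulate_expression <- function(n_genes = 2000, n_tissues = 5,
                                samples_per_tissue = 40,
                                overexpressed_sets = NULL,
                                n_overexpressed_per_tissue = 20,
                                log_fold_change = 1, noise_sd = 0.5,
                                baseline_mean = 5, baseline_sd = 1,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("gene%05d", seq_len(n_genes))
  tissues <- sprintf("tissue%d", seq_len(n_tissues))
  if (is.null(overexpressed_sets)) {
    if (n_overexpressed_per_tissue * n_tissues > n_genes) {
      stop("not enough genes to plant disjoint overexpressed sets")
    }
    picks <- sample(genes, n_overexpressed_per_tissue * n_tissues)
    overexpressed_sets <- split(picks, rep(tissues,
                                           each = n_overexpressed_per_tissue))
  }
  unknown <- setdiff(unlist(overexpressed_sets), genes)
  if (length(unknown)) {
    stop("overexpressed set references unknown gene(s): ",
         paste(utils::head(unknown, 3), collapse = ", "))
  }
  tissue_of_sample <- rep(tissues, each = samples_per_tissue)
  samples <- sprintf("%s_s%02d", tissue_of_sample,
                     sequence(rep(samples_per_tissue, n_tissues)))
  baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
  vals <- matrix(baseline, nrow = n_genes, ncol = length(samples))
  for (tt in names(overexpressed_sets)) {
    gi <- match(overexpressed_sets[[tt]], genes)
    si <- which(tissue_of_sample == tt)
    vals[gi, si] <- vals[gi, si] + log_fold_change
  }
  if (noise_sd > 0) {
    vals <- vals + matrix(stats::rnorm(length(vals), 0, noise_sd),
                          nrow = n_genes)
  }
  em <- expression_matrix(genes, samples, tissue_of_sample, vals)
  attr(em, "ground_truth") <- list(overexpressed_sets = overexpressed_sets,
                                   log_fold_change = log_fold_change,
                                   noise_sd = noise_sd)
  em
}

#' Write a ground-truth manifest for a synthetic data set
#' @param manifest Named list (sweep positions, planted sets, planted rho,
#'   seed, ...).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
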