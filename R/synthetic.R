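#' Default loading pattern of the seven lifestyle indicators
#'
#' Three latent factors drive the seven indicators: house modernity loads
#' on the four construction/infrastructure codes (wall, floor, water,
#' latrine), subsistence items on the traditional-item ownership
#' proportion, and power usage on electricity access plus the market-item
#' ownership proportion.
#'
#' @return 7 x 3 numeric matrix of loadings.
#' @export
default_loadings <- function() {
  L <- rbind(
    wall            = c(0.85, -0.25, 0.10),
    floor           = c(0.80, -0.25, 0.10),
    water           = c(0.60, -0.35, 0.15),
    latrine         = c(0.60, -0.10, 0.15),
    electricity     = c(0.15, -0.45, 0.75),
    sol_traditional = c(-0.25, 0.85, 0.00),
    sol_market      = c(0.10, 0.05, 0.85))
  colnames(L) <- c("modernity", "subsistence", "power")
  L
}

#' Configuration of the synthetic gut-microbiome study
#'
#' Bundles every knob of the generator: cohort layout (213 participants in
#' five villages across two regions), the loading pattern tying seven
#' lifestyle indicators to three latent market-integration factors, the
#' effect sizes linking the modernity factor to community richness
#' (`pd_slope`), within-gradient heterogeneity (`disp_slope`) and its
#' power-usage modulation (`interaction`), and the lognormal library-size
#' distribution spanning roughly 20,000 to 2,600,000 reads.
#'
#' @param n_samples number of participants (default 213).
#' @param n_villages number of villages (default 5; the first two form the
#'   low-travel-time region `"uv"`, the rest region `"cc"`).
#' @param n_taxa number of OTUs on the simulated tree (default 250).
#' @param seed master seed; sub-streams for tree, metadata, and
#'   communities are derived from it.
#' @param true_loadings 7 x 3 loading matrix (default [default_loadings()]).
#' @param indicator_noise_sd per-indicator noise sd; `NULL` (default) uses
#'   `sqrt(1 - communality)` so indicators have unit variance.
#' @param pd_slope effect (on the log-odds of environmental-taxon access)
#'   of the modernity factor; negative values shrink the accessible taxon
#'   pool as modernity rises (default -0.6).
#' @param disp_slope effect of modernity on the log Dirichlet
#'   concentration; positive values make high-modernity communities more
#'   heterogeneous (default 0.5).
#' @param interaction power-usage modulation of both slopes (default 0.3).
#' @param region_shift 2 x 3 matrix of per-region offsets added to the
#'   latent factor scores (rows `uv`, `cc`).
#' @param depth_log_mean,depth_log_sd lognormal library-size parameters
#'   (defaults `log(168951)` and 0.95, matching a median near 169,000
#'   reads with a min/max spanning roughly 21,000 to 2,600,000).
#' @param depth_min depths are redrawn until at least this value, so all
#'   simulated samples survive the standard read filter (default 20843).
#' @param base_theta Dirichlet concentration at factor score 0
#'   (default 40).
#' @param env_frac fraction of taxa flagged as environmentally acquired
#'   and hence subject to modernity-dependent loss (default 0.5).
#' @param pool_base_logit baseline log-odds that an environmental taxon is
#'   accessible (default `qlogis(0.7)`).
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 213, n_villages = 5, n_taxa = 250,
                       seed = 1, true_loadings = default_loadings(),
                       indicator_noise_sd = NULL,
                       pd_slope = -0.6, disp_slope = 0.5, interaction = 0.3,
                       region_shift = rbind(uv = c(0.55, -0.40, 0.55),
                                            cc = c(-0.37, 0.27, -0.37)),
                       depth_log_mean = log(168951), depth_log_sd = 0.95,
                       depth_min = 20843, base_theta = 40, env_frac = 0.5,
                       pool_base_logit = stats::qlogis(0.7)) {
  stopifnot(n_samples >= 4, n_taxa >= 8, n_villages >= 2,
            depth_log_sd >= 0, nrow(true_loadings) == 7,
            ncol(true_loadings) == 3, base_theta > 0,
            env_frac > 0, env_frac < 1)
  cfg <- list(n_samples = as.integer(n_samples),
              n_villages = as.integer(n_villages),
              n_taxa = as.integer(n_taxa), seed = as.integer(seed),
              true_loadings = true_loadings,
              indicator_noise_sd = indicator_noise_sd,
              pd_slope = pd_slope, disp_slope = disp_slope,
              interaction = interaction, region_shift = region_shift,
              depth_log_mean = depth_log_mean, depth_log_sd = depth_log_sd,
              depth_min = depth_min, base_theta = base_theta,
              env_frac = env_frac, pool_base_logit = pool_base_logit)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate participant metadata and its latent ground truth
#'
#' Draws latent factor scores (standard normal, then region-shifted),
#' builds the seven lifestyle indicators as noisy linear combinations of
#' the scores, discretizes the house-construction indicators to ordered
#' codes by quantile binning, and maps the two ownership indicators to
#' item-list proportions in `[0, 1]` (6 traditional and 12 market items).
#'
#' @param cfg a [sim_config()].
#' @return list with `metadata` (data frame: sample_id, village, region,
#'   age, travel_rank, the 5 house codes, sol_traditional, sol_market) and
#'   `truth` (latent scores before/after region shift, environmental-taxon
#'   flags, modulated modernity exposure per sample).
#' @export
simulate_metadata <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_samples
  with_seed(substream_seed(cfg$seed, "metadata"), {
    villages <- c("UV1", "UV2", "CC1", "CC2", "CC3")[
      rep(seq_len(cfg$n_villages), length.out = n)]
    villages <- sort(villages)
    region <- ifelse(startsWith(villages, "UV"), "uv", "cc")
    travel_rank <- c(UV1 = 1, UV2 = 2, CC1 = 3, CC2 = 4, CC3 = 5)[villages]
    f_raw <- scale(matrix(rnorm(n * 3), n, 3))  # exact zero mean, unit sd
    attr(f_raw, "scaled:center") <- NULL; attr(f_raw, "scaled:scale") <- NULL
    f <- f_raw + cfg$region_shift[region, , drop = FALSE]
    colnames(f_raw) <- colnames(f) <- colnames(cfg$true_loadings)
    noise_sd <- cfg$indicator_noise_sd %||%
      sqrt(pmax(1 - rowSums(cfg$true_loadings^2), 0))
    noise_sd <- rep(noise_sd, length.out = 7)
    Y <- f %*% t(cfg$true_loadings) +
      matrix(rnorm(n * 7), n, 7) %*% diag(noise_sd)
    colnames(Y) <- rownames(cfg$true_loadings)
    codes <- function(y, levels) {
      br <- unique(quantile(y, probs = seq(0, 1, length.out = levels + 1)))
      cut(y, breaks = br, include.lowest = TRUE, labels = FALSE)
    }
    meta <- data.frame(
      sample_id = sprintf("S%03d", seq_len(n)),
      village = villages, region = region,
      age = pmin(round(1 + rgamma(n, shape = 1.7, scale = 15)), 100),
      travel_rank = as.numeric(travel_rank),
      wall = codes(Y[, "wall"], 4), floor = codes(Y[, "floor"], 4),
      water = codes(Y[, "water"], 4), latrine = codes(Y[, "latrine"], 4),
      electricity = codes(Y[, "electricity"], 3),
      sol_traditional = round(pnorm(Y[, "sol_traditional"]) * 6) / 6,
      sol_market = round(pnorm(Y[, "sol_market"]) * 12) / 12,
      stringsAsFactors = FALSE)
    rownames(meta) <- meta$sample_id
    env_taxon <- rep(FALSE, cfg$n_taxa)
    env_taxon[sample.int(cfg$n_taxa, round(cfg$env_frac * cfg$n_taxa))] <- TRUE
    rownames(f) <- rownames(f_raw) <- meta$sample_id
    # modernity exposure modulated by power usage: the single gradient that
    # drives both pool shrinkage and concentration loss
    exposure <- f[, 1] * (1 + cfg$interaction * f[, 3])
    truth <- list(scores = f, scores_unshifted = f_raw,
                  env_taxon = env_taxon, exposure = exposure)
    list(metadata = meta, truth = truth)
  })
}

#' Simulate OTU count tables with covariate-dependent structure
#'
#' For each participant the accessible taxon pool keeps all host-associated
#' taxa plus a modernity-dependent, nested subset of environmental taxa
#' (log-odds `pool_base_logit + pd_slope * exposure`), so expected
#' phylogenetic diversity falls as modernity rises. Composition is drawn
#' Dirichlet-multinomial with concentration
#' `theta_i = base_theta * exp(-disp_slope * exposure_i)`, so lower
#' concentration at high modernity provably inflates expected pairwise
#' distances. Library sizes are lognormal, truncated below at `depth_min`.
#'
#' @param tree a `phylo` tree whose tips cover the simulated taxa.
#' @param truth the `truth` element from [simulate_metadata()].
#' @param cfg the same [sim_config()].
#' @return integer count matrix (samples x OTUs) with attribute `"theta"`
#'   (per-sample Dirichlet concentration) and `"depths"`.
#' @export
simulate_communities <- function(tree, truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  tips <- tree$tip.label
  if (length(tips) < cfg$n_taxa)
    stop("tree has fewer tips than cfg$n_taxa", call. = FALSE)
  tips <- tips[seq_len(cfg$n_taxa)]
  n <- cfg$n_samples; m <- cfg$n_taxa
  with_seed(substream_seed(cfg$seed, "communities"), {
    base_abund <- rlnorm(m, 0, 1.5)
    env_order <- sample(which(truth$env_taxon))  # nested-loss ordering
    depths <- rlnorm(n, cfg$depth_log_mean, cfg$depth_log_sd)
    for (r in 1:20) {
      low <- depths < cfg$depth_min
      if (!any(low)) break
      depths[low] <- rlnorm(sum(low), cfg$depth_log_mean, cfg$depth_log_sd)
    }
    depths <- pmax(round(depths), cfg$depth_min)
    exposure <- truth$exposure
    keep_frac <- stats::plogis(cfg$pool_base_logit + cfg$pd_slope * exposure)
    theta <- cfg$base_theta * exp(-cfg$disp_slope * exposure)
    counts <- matrix(0L, n, m, dimnames = list(names(exposure), tips))
    n_env <- length(env_order)
    for (i in seq_len(n)) {
      accessible <- rep(TRUE, m)
      n_keep <- round(keep_frac[i] * n_env)
      if (n_keep < n_env)
        accessible[env_order[seq_len(n_env - n_keep)]] <- FALSE
      alpha <- base_abund[accessible]
      alpha <- theta[i] * alpha / sum(alpha)
      g <- rgamma(length(alpha), shape = alpha)
      if (sum(g) == 0) g[which.max(alpha)] <- 1
      counts[i, accessible] <- rmultinom(1, depths[i], g / sum(g))[, 1]
    }
    attr(counts, "theta") <- theta
    attr(counts, "depths") <- depths
    counts
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running [simulate_tree()], [simulate_metadata()] and
#' [simulate_communities()] with sub-seeds derived from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `tree`, `metadata`, `truth`, `counts`, and `config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  tree <- simulate_tree(cfg$n_taxa, seed = substream_seed(cfg$seed, "tree"))
  md <- simulate_metadata(cfg)
  counts <- simulate_communities(tree, md$truth, cfg)
  list(tree = tree, metadata = md$metadata, truth = md$truth,
       counts = counts, config = cfg)
}

#' Write a simulated study to plain-text files
#'
#' Emits the OTU table as TSV (samples in rows), the tree as newick, the
#' metadata and latent truth as CSV, and a JSON manifest recording the
#' configuration.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(otu = file.path(dir, "otu_table.tsv"),
             tree = file.path(dir, "tree.nwk"),
             meta = file.path(dir, "metadata.csv"),
             truth = file.path(dir, "truth.csv"),
             manifest = file.path(dir, "manifest.json"))
  write.table(data.frame(sample_id = rownames(sim$counts), sim$counts,
                         check.names = FALSE),
              paths["otu"], sep = "\t", quote = FALSE, row.names = FALSE)
  ape::write.tree(sim$tree, paths["tree"])
  write.csv(sim$metadata, paths["meta"], row.names = FALSE, quote = FALSE)
  truth_df <- data.frame(sample_id = rownames(sim$truth$scores),
                         sim$truth$scores,
                         exposure = sim$truth$exposure)
  write.csv(truth_df, paths["truth"], row.names = FALSE, quote = FALSE)
  cfg <- sim$config
  cfg$true_loadings <- as.data.frame(cfg$true_loadings)
  cfg$region_shift <- as.data.frame(cfg$region_shift)
  jsonlite::write_json(unclass(cfg), paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
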