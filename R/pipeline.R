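#' Read an OTU count table from TSV
#'
#' Expects samples in rows (first column = sample id, header = OTU ids),
#' the layout written by [write_simulation()].
#'
#' @param path TSV file path.
#' @return integer count matrix with sample ids as row names.
#' @export
read_otu_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  as_count_matrix(m)
}

#' Read an OTU count table from a BIOM file
#'
#' Thin wrapper around `biomformat::read_biom()` (JSON or HDF5 BIOM),
#' transposed to the samples-in-rows orientation used throughout this
#' package.
#'
#' @param path BIOM file path.
#' @return count matrix with sample ids as row names and OTU ids as
#'   column names.
#' @export
read_otu_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("reading BIOM files requires the 'biomformat' package",
         call. = FALSE)
  b <- biomformat::read_biom(path)
  m <- t(as.matrix(biomformat::biom_data(b)))
  as_count_matrix(m)
}

#' Cross-check OTU table, tree and metadata before analysis
#'
#' Verifies that every OTU in the table is a tree tip (fatal if not), that
#' table and metadata agree on sample ids (fatal), and flags tree tips
#' absent from the table or metadata columns with missing values
#' (warnings only).
#'
#' @param counts samples x OTUs count matrix.
#' @param tree `phylo` tree.
#' @param metadata per-sample data frame with a `sample_id` column or
#'   row names.
#' @return list with `errors` and `warnings` (character vectors); empty
#'   vectors mean a clean bundle.
#' @export
validate_inputs <- function(counts, tree, metadata) {
  errors <- character(); warnings <- character()
  otus <- colnames(counts)
  missing_tips <- setdiff(otus, tree$tip.label)
  if (length(missing_tips))
    errors <- c(errors, paste0("OTUs absent from tree: ",
                               paste(head(missing_tips, 5), collapse = ", ")))
  extra_tips <- setdiff(tree$tip.label, otus)
  if (length(extra_tips))
    warnings <- c(warnings, paste0(length(extra_tips),
                                   " tree tips not in the OTU table"))
  meta_ids <- metadata$sample_id %||% rownames(metadata)
  missing_meta <- setdiff(rownames(counts), meta_ids)
  if (length(missing_meta))
    errors <- c(errors, paste0("samples without metadata: ",
                               paste(head(missing_meta, 5), collapse = ", ")))
  n_incomplete <- sum(!complete.cases(metadata))
  if (n_incomplete > 0)
    warnings <- c(warnings, paste0(n_incomplete,
                                   " metadata rows have missing values"))
  list(errors = errors, warnings = warnings)
}

# Label varimax factors by their dominant indicator group, mirroring the
# naming of the three market-integration factors: house-construction codes
# -> modernity, traditional-item ownership -> subsistence, electricity +
# market items -> power.
label_factors <- function(loadings) {
  groups <- list(modernity = c("wall", "floor", "water", "latrine"),
                 subsistence = "sol_traditional",
                 power = c("electricity", "sol_market"))
  score <- sapply(groups, function(g)
    colSums(abs(loadings[intersect(g, rownames(loadings)), , drop = FALSE])))
  if (is.null(dim(score))) score <- matrix(score, nrow = 1,
                                           dimnames = list(NULL, names(groups)))
  labels <- rep(NA_character_, ncol(loadings))
  for (i in seq_len(min(ncol(loadings), length(groups)))) {
    best <- which(score == max(score, na.rm = TRUE), arr.ind = TRUE)[1, ]
    labels[best[1]] <- colnames(score)[best[2]]
    score[best[1], ] <- -Inf; score[, best[2]] <- -Inf
  }
  labels[is.na(labels)] <- paste0("factor", which(is.na(labels)))
  labels
}

#' Run the full market-integration microbiome analysis
#'
#' Orchestrates every stage: simulate (or load) data, filter low-depth
#' samples, normalise counts, extract latent lifestyle factors, compute
#' Faith's PD and weighted UniFrac distances, fit and select the PD
#' regression, evaluate windowed beta-dispersion per factor with a window
#' sweep, run PERMANOVA and region-conditioned db-RDA, and screen OTUs
#' against the factors with BY-corrected correlations. All randomness is
#' derived from one master seed, so identical configuration yields
#' byte-identical outputs.
#'
#' @param sim_cfg a [sim_config()] for synthetic input; mutually exclusive
#'   with `paths`.
#' @param paths named list (`otu_table`, `tree`, `metadata`) of input
#'   files; mutually exclusive with `sim_cfg`.
#' @param normalization `"rarefy"` (default) or `"sizefactor"`.
#' @param min_reads read filter threshold (default 20000).
#' @param rarefy_depth depth for rarefaction; `"auto"` uses the minimum
#'   retained library size.
#' @param window dispersion window fraction (default 0.05).
#' @param window_grid window sweep grid (default 0.025 to 0.10).
#' @param n_perm permutations for PERMANOVA and db-RDA (default 999).
#' @param alpha significance level for the OTU screen (default 0.05).
#' @param seed master seed (default `sim_cfg$seed` or 1).
#' @param out_dir if non-`NULL`, write all result tables (CSV) and a JSON
#'   manifest there.
#' @return list with elements `factors` (solution + labelled scores),
#'   `pd_table`, `pd_model` (selection object), `dispersion` (per-factor
#'   series), `window_sweep` (per-factor sensitivity tables), `permanova`,
#'   `dbrda`, `screen`, `n` (per-stage sample accounting), `config`.
#' @export
run_pipeline <- function(sim_cfg = NULL, paths = NULL,
                         normalization = c("rarefy", "sizefactor"),
                         min_reads = 20000, rarefy_depth = "auto",
                         window = 0.05,
                         window_grid = seq(0.025, 0.10, length.out = 7),
                         n_perm = 999, alpha = 0.05, seed = NULL,
                         out_dir = NULL) {
  normalization <- match.arg(normalization)
  if (is.null(sim_cfg) == is.null(paths))
    stop("provide exactly one of `sim_cfg` or `paths`", call. = FALSE)
  if (!is.null(sim_cfg)) {
    seed <- seed %||% sim_cfg$seed
    sim <- simulate_dataset(sim_cfg)
    counts <- sim$counts; tree <- sim$tree; metadata <- sim$metadata
  } else {
    seed <- seed %||% 1L
    counts <- read_otu_table(paths$otu_table)
    tree <- ape::read.tree(paths$tree)
    metadata <- read.csv(paths$metadata, stringsAsFactors = FALSE)
    rownames(metadata) <- metadata$sample_id
  }
  report <- validate_inputs(counts, tree, metadata)
  if (length(report$errors))
    stop("input validation failed:\n  ",
         paste(report$errors, collapse = "\n  "), call. = FALSE)
  for (w in report$warnings) message("validate_inputs: ", w)

  n_input <- nrow(counts)
  counts <- filter_samples(counts, min_reads = min_reads)
  n_filtered <- length(attr(counts, "removed"))
  metadata <- metadata[rownames(counts), , drop = FALSE]

  Z <- standardize_indicators(metadata)
  if (length(attr(Z, "dropped"))) {
    counts <- counts[rownames(Z), , drop = FALSE]
    metadata <- metadata[rownames(Z), , drop = FALSE]
  }

  norm_tab <- if (normalization == "rarefy") {
    depth <- if (identical(rarefy_depth, "auto")) min(rowSums(counts))
             else as.integer(rarefy_depth)
    rarefy(counts, depth, seed = substream_seed(seed, "rarefy"))
  } else size_factor_transform(counts)
  rel <- relative_abundance(norm_tab)

  bs <- branch_structure(tree)
  pd <- vapply(rownames(norm_tab), function(s)
    faith_pd(colnames(norm_tab)[norm_tab[s, ] > 0], bs), numeric(1))
  dist_mat <- pairwise_distances(rel, bs)

  fa <- select_num_factors(Z, direction = "stop_when_adequate")
  labels <- label_factors(fa$loadings)
  colnames(fa$loadings) <- colnames(fa$scores) <- labels
  scores <- fa$scores

  pd_table <- data.frame(sample_id = rownames(norm_tab), pd = pd,
                         scores[, intersect(c("modernity", "subsistence",
                                              "power"), labels),
                                drop = FALSE],
                         stringsAsFactors = FALSE)

  model_data <- data.frame(metadata[, c("age", "travel_rank", "region")],
                           scores, check.names = FALSE)
  model_data$region <- factor(model_data$region)
  full_terms <- c(intersect(c("modernity", "subsistence", "power"), labels),
                  "age", "travel_rank", "region")
  if (all(c("modernity", "power") %in% labels))
    full_terms <- c(full_terms, "modernity:power")
  pd_model <- backward_select(model_data, pd, full_terms)

  disp <- list(); sweep_tabs <- list(); disp_fits <- list()
  disp_seed <- substream_seed(seed, "dispersion")
  for (lab in labels) {
    f <- setNames(scores[, lab], rownames(scores))
    disp[[lab]] <- windowed_beta_dispersion(dist_mat, f, w = window)
    sweep_tabs[[lab]] <- window_sensitivity(dist_mat, f,
                                            fractions = window_grid,
                                            n_perm = n_perm,
                                            seed = disp_seed)
    hit <- which(abs(sweep_tabs[[lab]]$w - window) < 1e-12)
    disp_fits[[lab]] <- if (length(hit))
      sweep_tabs[[lab]][hit[1], , drop = FALSE]
    else window_sensitivity(dist_mat, f, fractions = window,
                            n_perm = n_perm, seed = disp_seed)
  }

  # interaction prediction profile: how power usage modulates the
  # PD-modernity line, when the selected model retains the interaction
  pd_profile <- NULL
  if ("modernity:power" %in% pd_model$terms)
    pd_profile <- prediction_profile(pd_model$fit, "modernity", "power",
                                     steps = 100)

  perm <- permanova(dist_mat, model_data, labels, n_perm = n_perm,
                    seed = substream_seed(seed, "permanova"))
  dbrda <- partial_dbrda(dist_mat,
                         constraints = as.data.frame(scores),
                         condition = model_data[, "region", drop = FALSE],
                         n_perm = n_perm,
                         seed = substream_seed(seed, "dbrda"))
  screen <- correlation_screen(rel, scores, alpha = alpha)

  result <- list(
    factors = fa, pd_table = pd_table, pd_model = pd_model,
    pd_profile = pd_profile,
    dispersion = disp, dispersion_fits = disp_fits,
    window_sweep = sweep_tabs, permanova = perm, dbrda = dbrda,
    screen = screen, distances = dist_mat,
    n = c(input = n_input, read_filtered = n_filtered,
          analyzed = nrow(norm_tab)),
    config = list(normalization = normalization, min_reads = min_reads,
                  window = window, n_perm = n_perm, alpha = alpha,
                  seed = seed))
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name)
    write.csv(df, file.path(out_dir, paste0(name, ".csv")),
              row.names = FALSE, quote = FALSE)
  wr(data.frame(indicator = rownames(result$factors$loadings),
                result$factors$loadings, check.names = FALSE),
     "factor_loadings")
  wr(data.frame(sample_id = rownames(result$factors$scores),
                result$factors$scores, check.names = FALSE), "factor_scores")
  wr(result$pd_table, "pd_table")
  if (!is.null(result$pd_profile)) wr(result$pd_profile, "pd_profile")
  disp_all <- do.call(rbind, lapply(names(result$dispersion), function(lab) {
    d <- result$dispersion[[lab]]; d$factor <- lab; d
  }))
  wr(disp_all, "dispersion")
  sweep_all <- do.call(rbind, lapply(names(result$window_sweep),
                                     function(lab) {
    d <- result$window_sweep[[lab]]; d$factor <- lab; d
  }))
  wr(sweep_all, "window_sensitivity")
  wr(as.data.frame(result$permanova), "permanova")
  wr(as.data.frame(result$screen), "otu_screen")
  manifest <- c(result$config,
                list(n = as.list(result$n),
                     dbrda = list(p = result$dbrda$p,
                                  pseudo_f = result$dbrda$pseudo_f,
                                  inertia = as.list(result$dbrda$inertia))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
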