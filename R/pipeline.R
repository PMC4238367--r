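#' Pipeline configuration
#'
#' Collects every tunable parameter of the structural, functional and
#' integration stages, pre-filled with the standard HD-MEA analysis
#' values: 64 x 64 grid at 42 um pitch, heat time `t = 25`, correlogram
#' bin 0.5 ms, velocity bound 400 mm/s, +-5 ms dithering repeated 100
#' times, significance level 0.05.
#'
#' @param n_rows,n_cols,pitch,f_s,pixels_per_um,offset_x,offset_y Grid and
#'   registration, see [electrode_grid()].
#' @param t Heat-diffusion time.
#' @param sc_threshold Structural-link threshold on the normalised heat
#'   map.
#' @param kappa_scale,eps,kappa_max Von Mises fitting, see [fit_vmm()].
#' @param edge_threshold,vote_threshold,min_length,max_gap,theta_step,dist_tol,max_segments
#'   Hough detector, see [hough_config()].
#' @param delta Correlogram bin width (s).
#' @param tau_max Correlogram lag window half-width (s).
#' @param v_max Velocity bound (mm/s).
#' @param jitter Dithering half-width (s).
#' @param reps Dithering repetitions per pair.
#' @param n_pairs Sampled pairs for the null model.
#' @param p Significance level.
#' @param seed Integer seed for every stochastic step.
#' @param include_diagonal Normalisation convention of the structural
#'   map.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_rows = 64L, n_cols = 64L, pitch = 42,
                            f_s = 7000, pixels_per_um = 1,
                            offset_x = 0, offset_y = 0,
                            t = 25, sc_threshold = 0.05,
                            kappa_scale = 10, eps = 1, kappa_max = 1e4,
                            edge_threshold = 0.4, vote_threshold = 5,
                            min_length = 4, max_gap = 2, theta_step = 3,
                            dist_tol = 1, max_segments = 8,
                            delta = 5e-4, tau_max = 0.05, v_max = 400,
                            jitter = 5e-3, reps = 100, n_pairs = 500,
                            p = 0.05, seed = 1L,
                            include_diagonal = FALSE) {
  structure(as.list(environment()), class = "pipeline_config")
}

config_grid <- function(cfg, t_r = NULL) {
  electrode_grid(cfg$n_rows, cfg$n_cols, cfg$pitch, cfg$f_s, t_r,
                 cfg$pixels_per_um, cfg$offset_x, cfg$offset_y)
}

config_hough <- function(cfg) {
  hough_config(cfg$edge_threshold, cfg$vote_threshold, cfg$min_length,
               cfg$max_gap, cfg$theta_step, cfg$dist_tol, cfg$max_segments)
}

#' Read / write a pipeline configuration as flat YAML
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  unknown <- setdiff(names(vals), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg[names(vals)] <- vals
  cfg
}

#' @rdname read_config
#' @param cfg A `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full structural + functional + integration analysis
#'
#' In-memory orchestration of the pipeline: structural prior from the
#' image and neuron map, functional graph from the spike trains,
#' structural refinement, accounting and (optionally) feature
#' classification.
#'
#' @param image Grayscale culture image matrix (or `NULL` to skip the
#'   image stage; then `structural` must be supplied).
#' @param spikes A [spike_train_set()].
#' @param neuron_map Per-electrode neuron counts; detected from the image
#'   when `NULL`.
#' @param config A [pipeline_config()].
#' @param classify Run the SVM feature ranking (default `FALSE`; it is
#'   the most expensive stage and needs enough links per class).
#' @param structural Optional precomputed [structural_prior()].
#' @return Object of class `mea_analysis`: `structural`, `functional`,
#'   `refined`, `accounting`, `features`, `ranking` (last two `NULL`
#'   unless `classify`), `config`.
#' @export
run_analysis <- function(image, spikes, neuron_map = NULL,
                         config = pipeline_config(), classify = FALSE,
                         structural = NULL) {
  grid <- spikes$grid
  if (is.null(structural)) {
    if (is.null(image)) stop("need either an image or a structural prior")
    structural <- structural_prior(
      image, grid, neuron_map, t = config$t,
      sc_threshold = config$sc_threshold, hough = config_hough(config),
      kappa_scale = config$kappa_scale, eps = config$eps,
      kappa_max = config$kappa_max,
      include_diagonal = config$include_diagonal)
  }
  functional <- functional_graph(
    spikes, delta = config$delta, tau_max = config$tau_max,
    v_max = config$v_max, n_pairs = config$n_pairs,
    jitter = config$jitter, reps = config$reps, p = config$p,
    seed = config$seed)
  refined <- refine_functional(functional, structural)
  report <- accounting_from_refined(refined)
  features <- NULL
  ranking <- NULL
  if (classify) {
    features <- extract_features(refined, spikes)
    ranking <- tryCatch(
      svm_feature_ranking(features, seed = config$seed),
      error = function(e) {
        warning("classification skipped: ", conditionMessage(e))
        NULL
      })
  }
  structure(list(structural = structural, functional = functional,
                 refined = refined, accounting = report,
                 features = features, ranking = ranking,
                 config = config),
            class = "mea_analysis")
}

#' @export
print.mea_analysis <- function(x, ...) {
  print(x$structural)
  print(x$functional)
  print(x$refined)
  print(x$accounting)
  if (!is.null(x$ranking)) print(x$ranking)
  invisible(x)
}

#' Precision / recall of estimated links against ground truth
#'
#' Compares an estimated set of unordered electrode pairs with the
#' ground-truth functional links of a [generate_network()].
#'
#' @param a,b Electrode indices of the estimated links.
#' @param net A `synthetic_network` (truth = its functional link pairs).
#' @return List with `precision`, `recall`, `tp`, `n_est`, `n_true`.
#' @export
link_recovery <- function(a, b, net) {
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  est <- unique(key(a, b))
  truth <- unique(key(net$links$index_a, net$links$index_b))
  tp <- sum(est %in% truth)
  list(precision = if (length(est) > 0) tp / length(est) else NA_real_,
       recall = if (length(truth) > 0) tp / length(truth) else NA_real_,
       tp = tp, n_est = length(est), n_true = length(truth))
}

#' Compare structural-prior refinement with correlation-only thresholding
#'
#' On a synthetic network with known functional links, evaluates the
#' refined (reweighted, `W >= W_s`) link set against the conventional
#' significance-only set (velocity-filtered, `C_P > C_s`, restricted to
#' neuron-bearing electrodes so both sets live on the same nodes).
#'
#' @param analysis A [run_analysis()] result.
#' @param net The `synthetic_network` the data came from.
#' @return List with `refined` and `cs_only` recovery metrics (see
#'   [link_recovery()]).
#' @export
compare_recovery <- function(analysis, net) {
  rl <- analysis$refined$links
  refined <- rl[rl$retained, , drop = FALSE]
  cs_only <- rl[rl$C_P > analysis$refined$C_s, , drop = FALSE]
  list(refined = link_recovery(refined$a, refined$b, net),
       cs_only = link_recovery(cs_only$a, cs_only$b, net))
}

#' Simulation study of structural-prior link recovery
#'
#' Generates a synthetic culture, renders its image, simulates spikes and
#' runs the full analysis, repeating over seeds, and reports per-seed
#' precision and recall of the refined versus significance-only link
#' sets. The default problem size -- a 16 x 16 sub-array with 100
#' neurons, a 300 s recording at 1 Hz background rate and a handful of
#' neuron-free noise electrodes -- is small enough to repeat many times
#' while preserving the statistical regime of a sparse culture.
#'
#' @param seeds Integer vector of seeds, one synthetic network per seed.
#' @param n_rows,n_cols,n_neurons Network size.
#' @param T_s Recording length (s).
#' @param bg_rate Background rate (Hz).
#' @param n_noise_electrodes Neuron-free spiking electrodes per network.
#' @param px_per_electrode Rendered patch side (pixels).
#' @param noise_level Image noise SD.
#' @param classify Also run the SVM feature ranking per seed.
#' @return Data frame with one row per seed: precision/recall of the
#'   refined and C_s-only sets, thresholds and stage counts.
#' @export
synthetic_recovery_study <- function(seeds = 1:10, n_rows = 16,
                                     n_cols = 16, n_neurons = 100,
                                     T_s = 300, bg_rate = 1,
                                     n_noise_electrodes = 15,
                                     px_per_electrode = 12,
                                     noise_level = 0.05,
                                     classify = FALSE) {
  out <- vector("list", length(seeds))
  for (k in seq_along(seeds)) {
    s <- as.integer(seeds[k])
    grid <- electrode_grid(n_rows, n_cols,
                           pixels_per_um = px_per_electrode / 42)
    net <- generate_network(n_neurons = n_neurons, grid = grid, seed = s)
    img <- render_image(net, px_per_electrode, noise_level = noise_level)
    spk <- simulate_spikes(net, T_s = T_s, bg_rate = bg_rate,
                           n_noise_electrodes = n_noise_electrodes,
                           seed = s)
    cfg <- pipeline_config(n_rows = n_rows, n_cols = n_cols,
                           pixels_per_um = px_per_electrode / 42,
                           seed = s)
    an <- run_analysis(img, spk, neuron_map = net$neuron_map,
                       config = cfg, classify = classify)
    cmp <- compare_recovery(an, net)
    out[[k]] <- data.frame(
      seed = s,
      precision_refined = cmp$refined$precision,
      recall_refined = cmp$refined$recall,
      precision_cs = cmp$cs_only$precision,
      recall_cs = cmp$cs_only$recall,
      n_refined = cmp$refined$n_est,
      n_cs = cmp$cs_only$n_est,
      n_true = cmp$refined$n_true,
      C_s = an$refined$C_s, W_s = an$refined$W_s,
      fc_initial = an$refined$counts$fc_initial,
      fc_pruned = an$refined$counts$fc_pruned,
      acc_eta = if (classify && !is.null(an$ranking)) an$ranking$acc_eta else NA_real_,
      top_acc = if (classify && !is.null(an$ranking)) max(an$ranking$results$mean_acc) else NA_real_)
  }
  do.call(rbind, out)
}

#' Export the refined graph as GraphML
#' @param rg A `refined_graph`.
#' @param grid An `electrode_grid`.
#' @param path Output path.
#' @param retained_only Export only retained links (default `TRUE`).
#' @export
write_graphml <- function(rg, grid, path, retained_only = TRUE) {
  l <- rg$links
  if (retained_only) l <- l[l$retained, , drop = FALSE]
  nodes <- sort(unique(c(l$a, l$b)))
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  igraph::V(g)$name <- as.character(nodes)
  igraph::V(g)$row <- (nodes - 1L) %/% grid$n_cols + 1L
  igraph::V(g)$col <- (nodes - 1L) %% grid$n_cols + 1L
  if (nrow(l) > 0) {
    g <- igraph::add_edges(g, rbind(match(l$a, nodes), match(l$b, nodes)))
    igraph::E(g)$weight <- l$W
    igraph::E(g)$C_P <- l$C_P
    igraph::E(g)$d_um <- ifelse(is.finite(l$d_um), l$d_um, -1)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Null-model summary as JSON
#' @param null A `null_model`.
#' @param path Output JSON path.
#' @export
write_null_summary <- function(null, path) {
  jsonlite::write_json(list(
    C_s = null$C_s, p = null$p, reps = null$reps,
    n_pairs = null$n_pairs, jitter_s = null$jitter, seed = null$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
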