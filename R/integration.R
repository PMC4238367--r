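#' Remove electrodes without neurons from a functional link table
#'
#' Functional graphs estimated purely from spikes can include electrodes
#' with no neuron in their recording area (spike-detection noise, strong
#' dendritic arborisation). The first refinement stage discards such nodes
#' and every incident link.
#'
#' @param links A [functional_links()]-style data frame with electrode
#'   index columns `a`, `b`.
#' @param neuron_map Integer vector of per-electrode neuron counts; must
#'   cover every electrode appearing in `links`.
#' @return List with `links` (the retained rows), `removed_links`,
#'   `removed_nodes`.
#' @export
prune_no_neuron_nodes <- function(links, neuron_map) {
  nodes <- unique(c(links$a, links$b))
  if (length(nodes) > 0 &&
      (max(nodes) > length(neuron_map) || min(nodes) < 1)) {
    stop("neuron map does not cover all functional-graph nodes")
  }
  if (anyNA(neuron_map[nodes])) {
    stop("neuron map has missing entries for functional-graph nodes")
  }
  keep <- neuron_map[links$a] > 0 & neuron_map[links$b] > 0
  bad_nodes <- nodes[neuron_map[nodes] == 0]
  list(links = links[keep, , drop = FALSE],
       removed_links = sum(!keep),
       removed_nodes = length(bad_nodes))
}

#' Structural-distance reweighting of a functional peak
#'
#' `W = C_P_tilde ^ (1 + d_norm)` for a normalised cross-correlation peak
#' and a normalised structural distance, both in \[0, 1\]. The weight is
#' monotone increasing in the peak and decreasing in distance, and weaker
#' correlations are penalised more strongly with distance than stronger
#' ones (for fixed `d > 0` the relative penalty `W / C_P_tilde` increases
#' with `C_P_tilde`) -- unlike a negative-exponential weighting
#' `C_P * exp(-d)`, which applies the same relative penalty at every
#' correlation level.
#'
#' @param cp_tilde Normalised peak(s) in \[0, 1\].
#' @param d_norm Normalised structural distance(s) in \[0, 1\].
#' @return Reweighted link weight(s) `W` in \[0, 1\], `W <= cp_tilde`.
#' @export
reweight <- function(cp_tilde, d_norm) {
  if (any(cp_tilde < 0 | cp_tilde > 1, na.rm = FALSE) || anyNA(cp_tilde)) {
    stop("cp_tilde must lie in [0, 1]")
  }
  if (any(d_norm < 0 | d_norm > 1) || anyNA(d_norm)) {
    stop("d_norm must lie in [0, 1]")
  }
  cp_tilde^(1 + d_norm)
}

# Look up normalised structural distances for electrode index pairs.
# Pairs with an endpoint outside the structural seed set, or with no
# structural path, get the maximum distance 1 and an unreachable flag.
structural_d_norm <- function(sg, a, b) {
  key <- as.character(sg$seeds)
  ia <- match(as.character(a), key)
  ib <- match(as.character(b), key)
  d <- rep(1, length(a))
  flag <- rep(TRUE, length(a))
  ok <- !is.na(ia) & !is.na(ib)
  if (any(ok)) {
    d[ok] <- sg$d_norm[cbind(ia[ok], ib[ok])]
    flag[ok] <- sg$unreachable[cbind(ia[ok], ib[ok])]
  }
  list(d_norm = d, unreachable = flag)
}

#' Refine a functional graph with the structural prior
#'
#' Second-stage refinement: starting from the unthresholded,
#' velocity-filtered functional links, (1) electrodes without neurons are
#' pruned, (2) peaks are normalised to \[0, 1\] by the maximum peak over
#' the surviving links and structural distances by the maximum finite
#' shortest-path distance, (3) each link is reweighted as
#' `W = C_P_tilde^(1 + d_norm)`, and (4) the dithering null model is
#' passed through the same normalisation and reweighting (each null peak
#' paired with the structural distance of its own sampled electrode pair)
#' to yield the reweighted significance threshold `W_s` at the same
#' p-value. A link is retained iff `W >= W_s`.
#'
#' @param fg A [functional_graph()].
#' @param sp A [structural_prior()] (or any object with `graph` =
#'   `structural_graph` and `neuron_map`).
#' @return Object of class `refined_graph`: `links` data frame (`a`, `b`,
#'   `C_P`, `C_tilde`, `d_um`, `d_norm`, `unreachable`, `W`, `retained`,
#'   plus the columns of the input links), `W_s`, `C_s`, `cp_max`,
#'   `counts` (stage accounting), `p`.
#' @export
refine_functional <- function(fg, sp) {
  stopifnot(inherits(fg, "functional_graph"))
  sg <- sp$graph
  all_links <- fg$links
  initial <- all_links[all_links$passed_velocity, , drop = FALSE]
  pr <- prune_no_neuron_nodes(initial, sp$neuron_map)
  links <- pr$links
  if (nrow(links) == 0) stop("no functional link survives pruning")
  cp_max <- max(links$C_P)
  if (cp_max <= 0) stop("all surviving peaks are zero")
  links$C_tilde <- links$C_P / cp_max
  dn <- structural_d_norm(sg, links$a, links$b)
  links$d_norm <- dn$d_norm
  links$unreachable <- dn$unreachable
  key <- as.character(sg$seeds)
  ia <- match(as.character(links$a), key)
  ib <- match(as.character(links$b), key)
  links$d_um <- ifelse(!is.na(ia) & !is.na(ib), sg$d_um[cbind(ia, ib)], Inf)
  links$W <- reweight(links$C_tilde, links$d_norm)

  null <- fg$null
  # the reweighted null lives on the same universe as the links it
  # thresholds: null pairs with a pruned (no-neuron) electrode would
  # carry the maximal distance penalty and bias W_s downwards
  np <- null$peaks[sp$neuron_map[null$peaks$a] > 0 &
                   sp$neuron_map[null$peaks$b] > 0, , drop = FALSE]
  if (nrow(np) == 0) np <- null$peaks
  ncp <- pmin(np$peak / cp_max, 1)
  ndn <- structural_d_norm(sg, np$a, np$b)
  w_null <- reweight(ncp, ndn$d_norm)
  W_s <- unname(stats::quantile(w_null, 1 - null$p, type = 1))
  links$retained <- links$W >= W_s

  counts <- list(
    neurons = sum(sp$neuron_map),
    sc_links = nrow(sg$edges),
    fc_initial = nrow(initial),
    fc_above_cs = sum(initial$C_P > null$C_s),
    fc_pruned = nrow(links),
    fc_pruned_above_cs = sum(links$C_P > null$C_s),
    fc_final = sum(links$retained)
  )
  structure(list(links = links, W_s = W_s, C_s = null$C_s,
                 cp_max = cp_max, counts = counts, p = null$p,
                 pruning = pr[c("removed_links", "removed_nodes")]),
            class = "refined_graph")
}

#' @export
print.refined_graph <- function(x, ...) {
  cat(sprintf(
    "<refined_graph> %d links in, %d retained (W_s = %.4g, C_s = %.4g)\n",
    x$counts$fc_initial, x$counts$fc_final, x$W_s, x$C_s))
  invisible(x)
}

#' Stage-count accounting report
#'
#' Summarises the pipeline stages in the standard per-network accounting
#' form: raw counts plus the derived reduction percentages. Discard
#' percentages are reported to one decimal; the pruning reduction is
#' reported as a whole-percent figure (the convention used when quoting
#' how much node pruning shrinks the graph).
#'
#' @param fc_initial Functional links in the initial estimate (after
#'   spatio-temporal filtering).
#' @param fc_above_cs Links above the significance threshold `C_s`.
#' @param fc_pruned Links remaining after removing no-neuron electrodes.
#' @param fc_pruned_above_cs Pruned links above `C_s`.
#' @param fc_final Final links (reweighted, above `W_s`).
#' @param neurons,sc_links Optional structural counts for the report.
#' @param discarded_at_cs,discarded_final Optional explicit discarded
#'   counts. When omitted they are derived as `fc_initial - fc_above_cs`
#'   and `fc_initial - fc_final`; published summary tables sometimes
#'   print the discarded counts themselves, so supplying them directly
#'   reproduces the printed percentages even when a table row does not
#'   tally exactly with its retained-count row.
#' @return Object of class `accounting_report`: list of counts and
#'   derived quantities `discarded_at_cs` (+ `pct_discarded_at_cs`),
#'   `pruning_reduction_pct`, `discarded_final` (+ `pct_discarded_final`).
#' @export
accounting <- function(fc_initial, fc_above_cs = NA, fc_pruned = NA,
                       fc_pruned_above_cs = NA, fc_final = NA,
                       neurons = NA, sc_links = NA,
                       discarded_at_cs = NA, discarded_final = NA) {
  stopifnot(fc_initial >= 0)
  pct1 <- function(x, total) round(100 * x / total, 1)
  rep <- list(
    neurons = neurons, sc_links = sc_links,
    fc_initial = fc_initial, fc_above_cs = fc_above_cs,
    fc_pruned = fc_pruned, fc_pruned_above_cs = fc_pruned_above_cs,
    fc_final = fc_final)
  if (is.na(discarded_at_cs) && !is.na(fc_above_cs)) {
    stopifnot(fc_above_cs <= fc_initial)
    discarded_at_cs <- fc_initial - fc_above_cs
  }
  if (!is.na(discarded_at_cs)) {
    stopifnot(discarded_at_cs >= 0, discarded_at_cs <= fc_initial)
    rep$discarded_at_cs <- discarded_at_cs
    rep$pct_discarded_at_cs <- pct1(discarded_at_cs, fc_initial)
  }
  if (!is.na(fc_pruned)) {
    stopifnot(fc_pruned <= fc_initial)
    rep$pruning_reduction_pct <- round(100 * (fc_initial - fc_pruned) / fc_initial)
  }
  if (is.na(discarded_final) && !is.na(fc_final)) {
    stopifnot(fc_final <= fc_initial)
    discarded_final <- fc_initial - fc_final
  }
  if (!is.na(discarded_final)) {
    stopifnot(discarded_final >= 0, discarded_final <= fc_initial)
    rep$discarded_final <- discarded_final
    rep$pct_discarded_final <- pct1(discarded_final, fc_initial)
  }
  structure(rep, class = "accounting_report")
}

#' @export
print.accounting_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "-" else format(v)
  cat("Accounting report\n")
  cat("  Neurons:                          ", fmt(x$neurons), "\n")
  cat("  SC links:                         ", fmt(x$sc_links), "\n")
  cat("  FC links (initial estimate):      ", fmt(x$fc_initial), "\n")
  cat("  FC links above C_s:               ", fmt(x$fc_above_cs), "\n")
  if (!is.null(x$discarded_at_cs)) {
    cat(sprintf("  Discarded at C_s:                  %d (%.1f%%)\n",
                x$discarded_at_cs, x$pct_discarded_at_cs))
  }
  cat("  FC links (neurons only):          ", fmt(x$fc_pruned), "\n")
  if (!is.null(x$pruning_reduction_pct)) {
    cat(sprintf("  Pruning reduction:                 %d%%\n",
                x$pruning_reduction_pct))
  }
  cat("  FC links (neurons only, > C_s):   ", fmt(x$fc_pruned_above_cs), "\n")
  cat("  FC links (final, above W_s):      ", fmt(x$fc_final), "\n")
  if (!is.null(x$discarded_final)) {
    cat(sprintf("  Discarded (final vs initial):      %d (%.1f%%)\n",
                x$discarded_final, x$pct_discarded_final))
  }
  invisible(x)
}

#' Accounting report from a refined graph
#' @param rg A [refine_functional()] result.
#' @return An [accounting()] report built from the pipeline's own stage
#'   counts.
#' @export
accounting_from_refined <- function(rg) {
  c <- rg$counts
  accounting(fc_initial = c$fc_initial, fc_above_cs = c$fc_above_cs,
             fc_pruned = c$fc_pruned,
             fc_pruned_above_cs = c$fc_pruned_above_cs,
             fc_final = c$fc_final, neurons = c$neurons,
             sc_links = c$sc_links)
}

#' Export a refined edge list
#' @param rg A `refined_graph`.
#' @param grid An `electrode_grid`.
#' @param path Output CSV path.
#' @export
write_refined_edges <- function(rg, grid, path) {
  l <- rg$links
  out <- data.frame(
    row_a = (l$a - 1L) %/% grid$n_cols + 1L,
    col_a = (l$a - 1L) %% grid$n_cols + 1L,
    row_b = (l$b - 1L) %/% grid$n_cols + 1L,
    col_b = (l$b - 1L) %% grid$n_cols + 1L,
    C_P = l$C_P, C_tilde = l$C_tilde, C_tau_ms = l$C_tau * 1e3,
    C_O = l$C_O, C_H = l$C_H, d_um = l$d_um, d_norm = l$d_norm,
    unreachable = l$unreachable, W = l$W, retained = l$retained)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
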