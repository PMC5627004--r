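#' Simulate a complete DNA-SIP experiment and call enriched taxa
#'
#' End-to-end convenience wrapper reproducing the statistical design of a
#' substrate-labeling SIP study: one community is run through two gradients
#' — a labeled incubation (labeled taxa at `atom13c`) and an unlabeled
#' control incubation — plus an unfractionated control. Heavy windows are
#' selected per gradient from detectability, window counts pooled, and the
#' two-control fold-enrichment rule applied.
#'
#' The default scenario is the package's reference condition: 100 taxa with
#' log-normal abundances and G+C uniform in `[0.35, 0.62]`; three fully
#' labeled degrader taxa at 2.5/2/2% abundance with G+C in `[0.50, 0.53]`
#' (their labeled bands, 1.745--1.748 g/mL, clear the unlabeled background);
#' and a high-G+C confounder (gc 0.67, 10% abundance, unlabeled) that
#' dominates the control heavy window the way a high-G+C genus does in a
#' real gradient. 20 fractions over 1.66--1.78 g/mL; heavy windows three
#' fractions (~0.018 g/mL, comparable to the ~0.01 g/mL windows of real
#' gradients) wide so every labeled band is covered evenly; depth 1e4 reads
#' per fraction.
#'
#' @param n_taxa Community size.
#' @param n_labeled Number of labeled (substrate-assimilating) taxa.
#' @param labeled_abundance Base abundances of the labeled taxa.
#' @param labeled_gc_range G+C range of the labeled taxa.
#' @param gc_range G+C range of the unlabeled background.
#' @param confounder Include the high-G+C unlabeled confounder?
#' @param confounder_gc,confounder_abundance Confounder parameters.
#' @param atom13c 13C atom fraction of labeled taxa in the labeled run.
#' @param n_fractions,density_range,sigma_rho,total_dna Gradient parameters,
#'   see [simulate_gradient()].
#' @param depth Amplicon depth per fraction (and for the unfractionated
#'   control).
#' @param detection_threshold PCR detectability threshold (fraction of loaded
#'   DNA).
#' @param window_width Heavy-window width in fractions.
#' @param seed Integer seed controlling every random draw.
#' @return A list of class `sip_experiment` with elements `community`,
#'   `gradient_labeled`, `gradient_control`, `table_labeled`,
#'   `table_control`, `window_labeled`, `window_control`, `counts` (the three
#'   pooled tables) and `calls` (an `enrichment_calls` tibble).
#' @export
simulate_sip_experiment <- function(n_taxa = 100, n_labeled = 3,
                                    labeled_abundance = c(0.025, 0.02, 0.02),
                                    labeled_gc_range = c(0.50, 0.53),
                                    gc_range = c(0.35, 0.62),
                                    confounder = TRUE, confounder_gc = 0.67,
                                    confounder_abundance = 0.10,
                                    atom13c = 1,
                                    n_fractions = 20,
                                    density_range = c(1.66, 1.78),
                                    sigma_rho = 0.006, total_dna = 100,
                                    depth = 1e4, detection_threshold = 0.005,
                                    window_width = 3, seed = NULL) {
  stopifnot(n_labeled >= 1, length(labeled_abundance) == n_labeled)
  with_seed(seed, {
    ids <- sprintf("otu_%03d", seq_len(n_taxa))
    labeled_ids <- ids[seq_len(n_labeled)]
    ab_override <- setNames(labeled_abundance, labeled_ids)
    gc_override <- setNames(
      runif(n_labeled, labeled_gc_range[1], labeled_gc_range[2]), labeled_ids)
    if (confounder) {
      cid <- ids[n_labeled + 1L]
      ab_override <- c(ab_override, setNames(confounder_abundance, cid))
      gc_override <- c(gc_override, setNames(confounder_gc, cid))
    }

    community <- simulate_community(
      n_taxa, labeled_ids = labeled_ids, gc_range = gc_range,
      abundance = ab_override, gc = gc_override, atom13c = atom13c)

    community_ctrl <- dplyr::mutate(community, atom13c = 0)

    grad_lab <- simulate_gradient(community, n_fractions, density_range,
                                  sigma_rho, total_dna)
    grad_ctl <- simulate_gradient(community_ctrl, n_fractions, density_range,
                                  sigma_rho, total_dna)

    tab_lab <- simulate_amplicon_table(grad_lab, depth, detection_threshold)
    tab_ctl <- simulate_amplicon_table(grad_ctl, depth, detection_threshold)

    win_lab <- select_heavy_window(grad_lab, detection_threshold, window_width)
    win_ctl <- select_heavy_window(grad_ctl, detection_threshold, window_width)

    counts <- list(
      heavy = pool_fractions(tab_lab, win_lab),
      ctrl_heavy = pool_fractions(tab_ctl, win_ctl),
      ctrl_unfrac = simulate_unfractionated(community, depth)
    )
    calls <- call_all(counts$heavy, counts$ctrl_heavy, counts$ctrl_unfrac)

    structure(list(
      community = community,
      gradient_labeled = grad_lab, gradient_control = grad_ctl,
      table_labeled = tab_lab, table_control = tab_ctl,
      window_labeled = win_lab, window_control = win_ctl,
      counts = counts, calls = calls
    ), class = "sip_experiment")
  })
}

#' @export
print.sip_experiment <- function(x, ...) {
  n_enr <- sum(x$calls$enriched)
  truth <- x$community$taxon_id[x$community$labeled]
  cat("<sip_experiment>\n")
  cat(sprintf("  %d taxa (%d labeled), heavy window %.3f-%.3f g/mL\n",
              nrow(x$community), length(truth),
              min(x$window_labeled$density), max(x$window_labeled$density)))
  cat(sprintf("  %d taxa called enriched: %s\n", n_enr,
              paste(head(x$calls$taxon_id[x$calls$enriched], 10), collapse = ", ")))
  invisible(x)
}
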