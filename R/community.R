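#' Pool of plausible tailings-pond lineages
#'
#' A small table of named lineages (domain through genus) drawn from taxa
#' typically reported in oil sands process-affected water and other
#' hydrocarbon-impacted freshwater systems. [simulate_community()] recycles
#' these when it needs more taxa than the pool holds.
#'
#' @return A tibble with columns `domain`, `phylum`, `class`, `order`,
#'   `family`, `genus`.
#' @export
lineage_pool <- function() {
  g <- function(phylum, class, order, family, genus) {
    tibble::tibble(domain = "Bacteria", phylum = phylum, class = class,
                   order = order, family = family, genus = genus)
  }
  dplyr::bind_rows(
    g("Proteobacteria", "Betaproteobacteria", "Rhodocyclales", "Rhodocyclaceae", "Methyloversatilis"),
    g("Proteobacteria", "Betaproteobacteria", "Rhodocyclales", "Rhodocyclaceae", "Thauera"),
    g("Proteobacteria", "Betaproteobacteria", "Rhodocyclales", "Rhodocyclaceae", "Azoarcus"),
    g("Proteobacteria", "Betaproteobacteria", "Rhodocyclales", "Rhodocyclaceae", "Dechloromonas"),
    g("Proteobacteria", "Alphaproteobacteria", "Rhodospirillales", "Rhodospirillaceae", "Zavarzinia"),
    g("Proteobacteria", "Gammaproteobacteria", "Chromatiales", "Chromatiaceae", "Thiocapsa"),
    g("Proteobacteria", "Gammaproteobacteria", "Pseudomonadales", "Pseudomonadaceae", "Pseudomonas"),
    g("Proteobacteria", "Betaproteobacteria", "Burkholderiales", "Comamonadaceae", "Hydrogenophaga"),
    g("Proteobacteria", "Betaproteobacteria", "Burkholderiales", "Comamonadaceae", "Acidovorax"),
    g("Proteobacteria", "Betaproteobacteria", "Burkholderiales", "Comamonadaceae", "Rhodoferax"),
    g("Proteobacteria", "Betaproteobacteria", "Burkholderiales", "Comamonadaceae", "Polaromonas"),
    g("Proteobacteria", "Gammaproteobacteria", "Xanthomonadales", "Xanthomonadaceae", "Luteibacter"),
    g("Proteobacteria", "Gammaproteobacteria", "Pseudomonadales", "Moraxellaceae", "Enhydrobacter"),
    g("Proteobacteria", "Alphaproteobacteria", "Rhizobiales", "Hyphomicrobiaceae", "Devosia"),
    g("Proteobacteria", "Gammaproteobacteria", "Methylococcales", "Methylococcaceae", "Methylomonas"),
    g("Proteobacteria", "Alphaproteobacteria", "Caulobacterales", "Caulobacteraceae", "Brevundimonas"),
    g("Proteobacteria", "Alphaproteobacteria", "Sphingomonadales", "Sphingomonadaceae", "Sphingomonas"),
    g("Proteobacteria", "Alphaproteobacteria", "Sphingomonadales", "Sphingomonadaceae", "Novosphingobium"),
    g("Proteobacteria", "Alphaproteobacteria", "Rhizobiales", "Rhodobiaceae", "Parvibaculum"),
    g("Proteobacteria", "Betaproteobacteria", "Rhodocyclales", "Rhodocyclaceae", "Sulfuritalea"),
    g("Bacteroidetes", "Flavobacteriia", "Flavobacteriales", "Flavobacteriaceae", "Flavobacterium"),
    g("Bacteroidetes", "Chitinophagia", "Chitinophagales", "Chitinophagaceae", "Sediminibacterium"),
    g("Bacteroidetes", "Cytophagia", "Cytophagales", "Cyclobacteriaceae", "Algoriphagus"),
    g("Actinobacteria", "Actinomycetia", "Micrococcales", "Micrococcaceae", "Arthrobacter"),
    g("Actinobacteria", "Actinomycetia", "Mycobacteriales", "Mycobacteriaceae", "Mycobacterium"),
    g("Actinobacteria", "Actinomycetia", "Mycobacteriales", "Nocardiaceae", "Rhodococcus")
  )
}

#' Simulate a microbial community specification
#'
#' Draws a community of `n_taxa` taxa with log-normally distributed relative
#' abundances (normalised to sum to 1), per-taxon G+C content uniform within
#' `gc_range`, and a labeling state used by the stable-isotope probing (SIP)
#' simulators: labeled taxa carry a 13C atom fraction `atom13c`, all others
#' are at natural abundance (0).
#'
#' Named `abundance` or `gc` overrides pin individual taxa; remaining
#' abundances are rescaled so the community still sums to 1. Unnamed
#' overrides of length `n_taxa` replace the draw entirely.
#'
#' @param n_taxa Number of taxa (>= 2).
#' @param labeled_ids Character vector of taxon ids to mark as 13C-labeled;
#'   must be a subset of the generated ids (`otu_001`, `otu_002`, ...).
#' @param gc_range Length-2 range in `[0, 1]` for uniform G+C draws.
#' @param seed Integer seed; identical seeds give identical communities.
#' @param abundance Optional abundance override (unnamed length `n_taxa`, or
#'   named by taxon id).
#' @param gc Optional G+C override, same conventions as `abundance`.
#' @param atom13c 13C atom fraction assigned to labeled taxa (1 = fully
#'   labeled, as for 99 atom% 13C substrates).
#' @param sdlog Log-scale standard deviation of the abundance distribution.
#'
#' @return A tibble of class `sip_community` with columns `taxon_id`, the six
#'   taxonomy ranks, `gc`, `base_abundance`, `labeled`, `atom13c`.
#' @examples
#' comm <- simulate_community(10, labeled_ids = "otu_001", seed = 1)
#' sum(comm$base_abundance)
#' @export
simulate_community <- function(n_taxa, labeled_ids = NULL,
                               gc_range = c(0.35, 0.62), seed = NULL,
                               abundance = NULL, gc = NULL,
                               atom13c = 1, sdlog = 1) {
  if (!is.numeric(n_taxa) || n_taxa < 2) {
    stop("`n_taxa` must be at least 2: a community needs members", call. = FALSE)
  }
  n_taxa <- as.integer(n_taxa)
  if (length(gc_range) != 2 || gc_range[1] > gc_range[2]) {
    stop("`gc_range` must be an ascending length-2 range", call. = FALSE)
  }
  check_fraction(gc_range, "gc_range")
  check_fraction(atom13c, "atom13c")

  ids <- sprintf("otu_%03d", seq_len(n_taxa))
  labeled_ids <- labeled_ids %||% character(0)
  if (!all(labeled_ids %in% ids)) {
    stop("`labeled_ids` must be a subset of the generated taxon ids", call. = FALSE)
  }

  with_seed(seed, {
    ab <- resolve_override(abundance, ids, rlnorm(n_taxa, 0, sdlog),
                           renormalise = TRUE, name = "abundance")
    gcv <- resolve_override(gc, ids, runif(n_taxa, gc_range[1], gc_range[2]),
                            renormalise = FALSE, name = "gc")
    check_fraction(gcv, "gc")

    pool <- lineage_pool()
    idx <- ((seq_len(n_taxa) - 1L) %% nrow(pool)) + 1L
    lin <- pool[idx, ]
    # disambiguate recycled genera so lineages stay unique per taxon
    copy <- as.integer((seq_len(n_taxa) - 1L) %/% nrow(pool))
    lin$genus <- ifelse(copy > 0, paste0(lin$genus, "_", copy + 1L), lin$genus)

    out <- tibble::tibble(
      taxon_id = ids,
      lin,
      gc = gcv,
      base_abundance = ab,
      labeled = ids %in% labeled_ids,
      atom13c = ifelse(ids %in% labeled_ids, atom13c, 0)
    )
    class(out) <- c("sip_community", class(out))
    validate_community(out)
  })
}

# apply a (possibly named, possibly partial) override to a drawn vector
resolve_override <- function(override, ids, drawn, renormalise, name) {
  if (is.null(override)) {
    x <- drawn
  } else if (is.null(names(override))) {
    if (length(override) != length(ids)) {
      stop(sprintf("unnamed `%s` override must have length n_taxa", name), call. = FALSE)
    }
    x <- as.numeric(override)
  } else {
    if (!all(names(override) %in% ids)) {
      stop(sprintf("`%s` override names must be taxon ids", name), call. = FALSE)
    }
    x <- drawn
    fixed <- match(names(override), ids)
    if (renormalise) {
      rest <- setdiff(seq_along(ids), fixed)
      budget <- 1 - sum(override)
      if (budget < 0) stop("named abundance overrides exceed 1", call. = FALSE)
      x[rest] <- x[rest] / sum(x[rest]) * budget
    }
    x[fixed] <- as.numeric(override)
    if (renormalise) return(x)
  }
  if (renormalise) x <- x / sum(x)
  x
}

validate_community <- function(x) {
  if (anyDuplicated(x$taxon_id)) stop("taxon ids must be unique", call. = FALSE)
  if (abs(sum(x$base_abundance) - 1) > 1e-9) {
    stop("community abundances must sum to 1 (within 1e-9)", call. = FALSE)
  }
  check_fraction(x$gc, "gc")
  check_fraction(x$base_abundance, "base_abundance")
  check_fraction(x$atom13c, "atom13c")
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
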