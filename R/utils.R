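# internal helpers

# run expr with a temporary RNG state seeded at `seed`; NULL leaves the
# current stream untouched (used when a caller manages seeding itself)
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

check_fraction <- function(x, name, allow_zero = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    stop(sprintf("`%s` must be numeric with no missing values", name), call. = FALSE)
  }
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  if (!all(lo_ok & x <= 1)) {
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

check_dna <- function(x, name) {
  if (!is.character(x) || length(x) == 0 || any(is.na(x)) || any(nchar(x) == 0)) {
    stop(sprintf("`%s` must be one or more non-empty sequences", name), call. = FALSE)
  }
  if (any(grepl("[^ACGTNacgtn]", x))) {
    stop(sprintf("`%s` contains characters outside the DNA alphabet {A,C,G,T,N}", name),
         call. = FALSE)
  }
  invisible(toupper(x))
}

revcomp <- function(x) {
  vapply(x, function(s) {
    chars <- rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "", fixed = TRUE)[[1]])
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

taxonomy_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus")
}
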