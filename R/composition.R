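#' Membrane lipid composition
#'
#' Describes a model membrane as phospholipid percentages (relative to all
#' phospholipids) plus a cholesterol fraction (relative to all lipids).
#' Fatty-acyl tail bookkeeping is done per 100 phospholipids, i.e. against a
#' nominal 200 tails, which is the accounting the brain-membrane literature
#' prints; compositions whose phospholipid block sums slightly off 100 (the
#' diseased-like model tabulates to 101) are accepted with a warning up to
#' 1.5 percentage points.
#'
#' @param phospholipids Named numeric vector of phospholipid percentages,
#'   names drawn from (or added to) the species registry.
#' @param cholesterol Cholesterol percentage of all lipids, in `[0, 100)`.
#' @param species_table Species metadata with tail assignments.
#' @return A `membrane_composition` object.
#' @examples
#' membrane_composition(c(POPC = 37.5, SDPE = 62.5), cholesterol = 20)
#' composition_preset("healthy")
#' @export
membrane_composition <- function(phospholipids, cholesterol = 0,
                                 species_table = species_registry()) {
  if (is.null(names(phospholipids)) || any(names(phospholipids) == "")) {
    abort("`phospholipids` must be a named numeric vector.")
  }
  if (any(phospholipids < 0)) abort("Phospholipid percentages must be >= 0.")
  tot <- sum(phospholipids)
  if (abs(tot - 100) > 1.5) {
    abort(sprintf("Phospholipid percentages sum to %.2f; expected 100.", tot))
  }
  if (abs(tot - 100) > 0.5) {
    warn(sprintf("Phospholipid percentages sum to %.2f, not 100; tail percentages are kept on the nominal 200-tail basis.", tot))
  }
  if (cholesterol < 0 || cholesterol >= 100) {
    abort("`cholesterol` must lie in [0, 100).")
  }
  validate_species_table(species_table)
  known <- species_table$species[species_table$role == "lipid"]
  miss <- setdiff(names(phospholipids), known)
  if (length(miss)) {
    abort(paste0("Species with missing tail assignment: ",
                 paste(miss, collapse = ", ")))
  }
  structure(list(phospholipids = phospholipids,
                 cholesterol = cholesterol,
                 species_table = species_table),
            class = "membrane_composition")
}

#' @export
print.membrane_composition <- function(x, ...) {
  cat("<membrane_composition>\n")
  for (s in names(x$phospholipids)) {
    cat(sprintf("  %-6s %6.2f %% of phospholipids\n", s, x$phospholipids[[s]]))
  }
  cat(sprintf("  %-6s %6.2f %% of all lipids\n", "CHOL", x$cholesterol))
  invisible(x)
}

#' @export
tidy.membrane_composition <- function(x, ...) {
  bind_rows(
    tibble(species = names(x$phospholipids),
           percent = unname(x$phospholipids),
           basis = "phospholipids"),
    tibble(species = "CHOL", percent = x$cholesterol, basis = "all_lipids")
  )
}

#' Built-in membrane composition presets
#'
#' `"healthy"` and `"diseased"` encode the DHA-rich and DHA-poor
#' brain-membrane models (five phospholipids plus 33% cholesterol);
#' `"ternary_high_dha"` is the simplified POPC:SDPE:cholesterol 30:50:20
#' mixture, expressed as POPC 37.5 / SDPE 62.5 of phospholipids with 20%
#' cholesterol of all lipids (equivalent mole fractions).
#'
#' @param name Preset name.
#' @return A `membrane_composition`.
#' @export
composition_preset <- function(name = c("healthy", "diseased", "ternary_high_dha")) {
  name <- match.arg(name)
  switch(name,
    healthy = membrane_composition(
      c(DPPC = 21, DSPC = 7, DOPC = 15, SDPC = 21, SM = 36),
      cholesterol = 33),
    diseased = suppressWarnings(membrane_composition(
      c(DPPC = 33, DSPC = 15, DOPC = 11, SDPC = 6, SM = 36),
      cholesterol = 33)),
    ternary_high_dha = membrane_composition(
      c(POPC = 37.5, SDPE = 62.5), cholesterol = 20)
  )
}

#' Fatty-acyl tail census of a composition
#'
#' Counts tails per 100 phospholipids (each phospholipid contributes its two
#' tail labels; cholesterol contributes none) and derives the percentage of
#' each tail label on the nominal 200-tail basis.
#'
#' @param composition A [membrane_composition()].
#' @return A tibble with columns `tail`, `count` (per 100 phospholipids) and
#'   `percent` (of 200 tails).
#' @examples
#' tail_census(composition_preset("healthy"))
#' @export
tail_census <- function(composition) {
  stopifnot(inherits(composition, "membrane_composition"))
  sp <- composition$species_table
  ph <- composition$phospholipids
  rows <- purrr::map_dfr(names(ph), function(s) {
    r <- sp[sp$species == s, ]
    tibble(tail = c(r$tail_1, r$tail_2), count = ph[[s]])
  })
  rows %>%
    group_by(.data$tail) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    mutate(percent = .data$count / 2) %>%
    arrange(.data$tail)
}

#' DHA (C22:6) fraction of membrane fatty-acyl tails
#'
#' @param composition A [membrane_composition()].
#' @param rounding `"half_away"` (default; 10.5 reports as 11) or `"none"`.
#' @return A tibble with `exact` and `reported` percentages.
#' @examples
#' dha_tail_fraction(composition_preset("healthy"))
#' @export
dha_tail_fraction <- function(composition, rounding = c("half_away", "none")) {
  rounding <- match.arg(rounding)
  census <- tail_census(composition)
  exact <- sum(census$percent[census$tail == "C22:6"])
  reported <- if (rounding == "half_away") {
    sign(exact) * floor(abs(exact) + 0.5)
  } else exact
  tibble(tail = "C22:6", exact = exact, reported = reported)
}

# Largest-remainder apportionment with deterministic tie-break
# (larger remainder first, then lexicographic name order).
largest_remainder <- function(quota) {
  fl <- floor(quota)
  left <- round(sum(quota)) - sum(fl)
  rem <- quota - fl
  ord <- order(-rem, names(quota))
  add <- integer(length(quota))
  if (left > 0) add[ord[seq_len(left)]] <- 1L
  out <- as.integer(fl + add)
  names(out) <- names(quota)
  out
}

#' Apportion particle counts from a composition
#'
#' Splits `n_lipids` particles (cholesterol included) across the species of
#' a composition by the largest-remainder method, so counts always sum
#' exactly to `n_lipids`. Ties are broken deterministically by species name.
#'
#' @param composition A [membrane_composition()].
#' @param n_lipids Total number of lipid particles to apportion.
#' @return A tibble with `species` and integer `count`.
#' @examples
#' particle_counts(composition_preset("healthy"), 1000)
#' @export
particle_counts <- function(composition, n_lipids) {
  stopifnot(inherits(composition, "membrane_composition"))
  n_lipids <- as.integer(n_lipids)
  ph <- composition$phospholipids
  ph <- ph[ph > 0]
  if (n_lipids < length(ph) + (composition$cholesterol > 0)) {
    abort("`n_lipids` is smaller than the number of species present.")
  }
  chol_quota <- n_lipids * composition$cholesterol / 100
  ph_quota <- (n_lipids - chol_quota) * ph / sum(ph)
  quota <- c(ph_quota, if (composition$cholesterol > 0) c(CHOL = chol_quota))
  counts <- largest_remainder(quota)
  dropped <- names(counts)[counts == 0]
  if (length(dropped)) {
    warn(paste0("Species dropped at this particle count: ",
                paste(dropped, collapse = ", ")))
  }
  tibble(species = names(counts), count = unname(counts))
}
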