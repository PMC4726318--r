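#' Built-in species registry
#'
#' Tabulates the particle species used throughout the package: the adenosine
#' A2A and dopamine D2 receptors, the phospholipids of the model membranes
#' with their two fatty-acyl tails, and cholesterol (tail-less sterol).
#'
#' Tail labels follow lipid shorthand (carbons:double bonds). Sphingomyelin
#' is booked as one C16:0 acyl chain plus the sphingosine backbone counted as
#' a single saturated C18 chain (`C18:sph`); only tail rows that are robust
#' to this convention (C22:6 and C16:0) are relied on elsewhere.
#'
#' @return A tibble with columns `species`, `role`
#'   (`receptor_A2A`, `receptor_D2`, `lipid`, `sterol`), `tail_1`, `tail_2`
#'   and per-tail saturation class (`sat_1`, `sat_2`; `saturated` or
#'   `unsaturated`, `NA` for sterols/receptors).
#' @examples
#' species_registry()
#' @export
species_registry <- function() {
  tribble(
    ~species, ~role,           ~tail_1,    ~tail_2,  ~sat_1,       ~sat_2,
    "A2A",    "receptor_A2A",  NA,         NA,       NA,           NA,
    "D2",     "receptor_D2",   NA,         NA,       NA,           NA,
    "DPPC",   "lipid",         "C16:0",    "C16:0",  "saturated",  "saturated",
    "DSPC",   "lipid",         "C18:0",    "C18:0",  "saturated",  "saturated",
    "DOPC",   "lipid",         "C18:1",    "C18:1",  "unsaturated","unsaturated",
    "SDPC",   "lipid",         "C18:0",    "C22:6",  "saturated",  "unsaturated",
    "SDPE",   "lipid",         "C18:0",    "C22:6",  "saturated",  "unsaturated",
    "POPC",   "lipid",         "C16:0",    "C18:1",  "saturated",  "unsaturated",
    "SM",     "lipid",         "C18:sph",  "C16:0",  "saturated",  "saturated",
    "CHOL",   "sterol",        NA,         NA,       NA,           NA
  )
}

validate_species_table <- function(tab) {
  need <- c("species", "role", "tail_1", "tail_2", "sat_1", "sat_2")
  if (!all(need %in% names(tab))) {
    abort(paste0("Species table must have columns: ",
                 paste(need, collapse = ", ")))
  }
  lip <- tab[tab$role == "lipid", ]
  bad <- lip$species[is.na(lip$tail_1) | is.na(lip$tail_2)]
  if (length(bad)) {
    abort(paste0("Lipid species missing tail assignment: ",
                 paste(bad, collapse = ", ")))
  }
  st <- tab[tab$role == "sterol", ]
  if (any(!is.na(st$tail_1)) || any(!is.na(st$tail_2))) {
    abort("Sterol species must not carry tail labels.")
  }
  invisible(tab)
}

# Saturation class of the unsaturated/saturated split used in demixing
# analyses: the lipid-level class is 'unsaturated' if any tail is.
lipid_saturation_class <- function(species, registry = species_registry()) {
  idx <- match(species, registry$species)
  if (anyNA(idx)) {
    abort(paste0("Unknown species: ",
                 paste(unique(species[is.na(idx)]), collapse = ", ")))
  }
  ifelse(registry$role[idx] != "lipid", NA_character_,
         ifelse(registry$sat_1[idx] == "unsaturated" |
                  registry$sat_2[idx] == "unsaturated",
                "unsaturated", "saturated"))
}

species_role <- function(species, registry = species_registry()) {
  idx <- match(species, registry$species)
  out <- registry$role[idx]
  out[is.na(idx)] <- NA_character_
  out
}

is_receptor_role <- function(role) role %in% c("receptor_A2A", "receptor_D2")
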