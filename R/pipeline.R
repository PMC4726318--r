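#' Configure an end-to-end membrane study
#'
#' Bundles everything needed for a reproducible two-condition comparison:
#' which presets to run, how many seeded replicas, the contact cutoff and
#' analysis window, and simulator sizing. Seeds are always explicit in the
#' resulting object so every number in the report traces back to
#' `(config, seed)`.
#'
#' @param conditions Two preset names to compare (numerator first).
#' @param n_replicates Replicas per condition.
#' @param base_seed Seeds are `base_seed + 0:(n_replicates-1)` per
#'   condition (second condition offset by 1000).
#' @param cutoff Contact cutoff (nm).
#' @param window Analysis window or `NULL` for final third.
#' @param n_receptors,n_lipids,box_length,n_steps,stride,dt Passed to
#'   [sim_preset()].
#' @return A `study_config`.
#' @export
study_config <- function(conditions = c("healthy", "diseased"),
                         n_replicates = 3L, base_seed = 1L, cutoff = 4.2,
                         window = NULL, n_receptors = 18L, n_lipids = 150L,
                         box_length = 40, n_steps = 20000L, stride = 100L,
                         dt = 2e-4) {
  if (length(conditions) != 2) abort("`conditions` must name two presets.")
  if (cutoff <= 0) abort("`cutoff` must be > 0.")
  seeds <- list(base_seed + seq_len(n_replicates) - 1L,
                base_seed + 1000L + seq_len(n_replicates) - 1L)
  names(seeds) <- conditions
  structure(list(conditions = conditions, n_replicates = as.integer(n_replicates),
                 seeds = seeds, cutoff = cutoff, window = window,
                 sim = list(n_receptors = n_receptors, n_lipids = n_lipids,
                            box_length = box_length, n_steps = n_steps,
                            stride = stride, dt = dt)),
            class = "study_config")
}

#' Run the end-to-end study
#'
#' Simulates every `(condition, seed)` pair, then reports per-condition
#' contact kinetics with errors, the relative aggregation difference with a
#' replicate-level Welch test, per-species diffusion coefficients from MSD
#' fits, an all-lipid RDF/shell summary per condition, and the
#' saturated-unsaturated mixing fraction series. Deterministic given the
#' config; when `output_dir` is set, CSV/JSON artefacts are written there.
#'
#' @param config A [study_config()].
#' @param output_dir Optional directory for artefacts.
#' @param verbose Log stage progress.
#' @return A `study_report` list of tibbles with a provenance hash.
#' @export
run_study <- function(config, output_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  runs <- purrr::map(config$conditions, function(cond) {
    cfg <- sim_preset(cond, n_receptors = config$sim$n_receptors,
                      n_lipids = config$sim$n_lipids,
                      box_length = config$sim$box_length,
                      n_steps = config$sim$n_steps,
                      stride = config$sim$stride, dt = config$sim$dt)
    purrr::map(config$seeds[[cond]], function(s) {
      say("simulate: %s seed %d", cond, s)
      simulate_membrane(cfg, seed = s)
    })
  })
  names(runs) <- config$conditions
  trajs <- purrr::map(runs, ~ purrr::map(.x, "trajectory"))

  say("contacts")
  contact_summary <- purrr::imap_dfr(trajs, function(tr, cond) {
    cs <- contacts_per_protomer(tr, cutoff = config$cutoff,
                                window = config$window)
    mutate(glance(cs), condition = cond)
  })
  comparison <- compare_aggregation(trajs[[1]], trajs[[2]],
                                    cutoff = config$cutoff,
                                    window = config$window)
  if (config$n_replicates == 1) {
    comparison$error_mode <- "single-replica (block SEM, no replicate test)"
  }

  say("diffusion")
  diffusion <- purrr::imap_dfr(trajs, function(tr, cond) {
    species <- unique(tr[[1]]$species)
    purrr::map_dfr(species, function(sp) {
      ests <- purrr::map(tr, function(t1) {
        fit_diffusion(msd(unwrap_trajectory(t1), selection = sp,
                          origin_stride = 5L))
      })
      agg <- replica_aggregate(ests)
      tibble(condition = cond, species = sp, D_nm2_us = agg$D, se = agg$se,
             D_1e8_cm2_s = convert_units(agg$D, "nm2_us", "1e-8cm2_s"))
    })
  })

  say("lipid environment")
  lipid_species <- purrr::map(trajs, ~ setdiff(unique(.x[[1]]$species),
                                               c("A2A", "D2")))
  shells <- purrr::imap(trajs, function(tr, cond) {
    rdf <- rdf2d(tr[[1]], target = lipid_species[[cond]], bin_width = 0.1)
    list(rdf = rdf, shell = shell_report(rdf, tr[[1]]))
  })
  sat <- c("DPPC", "DSPC", "SM")
  unsat <- c("DOPC", "SDPC", "SDPE", "POPC")
  mixing <- purrr::imap_dfr(trajs, function(tr, cond) {
    cls_a <- intersect(sat, unique(tr[[1]]$species))
    cls_b <- intersect(unsat, unique(tr[[1]]$species))
    if (!length(cls_a) || !length(cls_b)) return(tibble())
    mutate(mixing_contact_fraction(tr[[1]], cls_a, cls_b),
           condition = cond)
  })

  provenance <- tibble(
    hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("memrate")),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  report <- structure(list(config = config, contact_summary = contact_summary,
                           comparison = comparison, diffusion = diffusion,
                           shells = shells, mixing = mixing,
                           provenance = provenance),
                      class = "study_report")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(contact_summary, file.path(output_dir, "contact_summary.csv"),
              row.names = FALSE)
    write.csv(diffusion, file.path(output_dir, "diffusion.csv"),
              row.names = FALSE)
    if (nrow(mixing)) {
      write.csv(mixing, file.path(output_dir, "mixing_fraction.csv"),
                row.names = FALSE)
    }
    jsonlite::write_json(
      list(comparison = comparison, provenance = provenance),
      file.path(output_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>", paste(x$config$conditions, collapse = " vs "), "\n")
  print(x$contact_summary)
  cat(sprintf("  relative aggregation difference: %+.1f%% (p = %.3g)\n",
              x$comparison$relative_difference_pct, x$comparison$p_value))
  invisible(x)
}

#' Write the small demonstration fixture set
#'
#' Produces deterministic fixtures used by examples and tests: a 9-dimer
#' receptor layout (mean contacts per protomer exactly 1), a 4-receptor
#' chain, a striped demixed two-species frame, and a noiseless hyperbolic
#' BRET plate as CSV.
#'
#' @param output_dir Writable directory.
#' @param seed Seed for the stochastic fixtures.
#' @return Invisibly, a tibble of written paths.
#' @export
make_demo_fixtures <- function(output_dir, seed = 1L) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(dimers = file.path(output_dir, "dimers.memtraj"),
             chain = file.path(output_dir, "chain.memtraj"),
             striped = file.path(output_dir, "striped.memtraj"),
             plate = file.path(output_dir, "bret_plate.csv"))
  write_trajectory(make_layout("dimers", n = 9, spacing = 4, n_frames = 3),
                   paths[["dimers"]])
  write_trajectory(make_layout("chain", n = 4, spacing = 4, n_frames = 3),
                   paths[["chain"]])
  write_trajectory(striped_frame(seed = seed), paths[["striped"]])
  tt <- synthesize_titration(bretmax = 100, bret50 = 0.5, noise = 0,
                             seed = seed)
  plate <- mutate(tt,
                  well = paste0("W", sprintf("%02d", dplyr::row_number())),
                  luminescence = 1000,
                  fluorescence = .data$bret / 1000 * .data$luminescence,
                  time_min = 1)
  write.csv(plate[, c("well", "condition", "x", "fluorescence",
                      "luminescence", "time_min")],
            paths[["plate"]], row.names = FALSE)
  invisible(tibble(name = names(paths), path = unname(paths)))
}

# A fully demixed two-phase frame: saturated lipids in the left half,
# unsaturated in the right, jittered off a grid.
striped_frame <- function(n_per_class = 100L, box = box_spec(c(25, 25)),
                          seed = 1L) {
  set.seed(seed)
  half <- box$lengths[1] / 2
  place <- function(x0, x1, n) {
    k <- ceiling(sqrt(n))
    g <- expand.grid(ix = seq_len(k) - 0.5, iy = seq_len(k) - 0.5)[seq_len(n), ]
    cbind(x0 + g$ix / k * (x1 - x0) + runif(n, -0.1, 0.1),
          g$iy / k * box$lengths[2] + runif(n, -0.1, 0.1))
  }
  a <- place(0, half, n_per_class)
  b <- place(half, box$lengths[1], n_per_class)
  df <- tibble(
    frame = 0L, time = 0,
    id = seq_len(2L * n_per_class),
    species = rep(c("DPPC", "DOPC"), each = n_per_class),
    x = wrap_coord(c(a[, 1], b[, 1]), box$lengths[1]),
    y = wrap_coord(c(a[, 2], b[, 2]), box$lengths[2]),
    theta = NA_real_
  )
  as_trajectory(df, box)
}

#' Read a BRET plate CSV
#'
#' Expects columns `x` (acceptor level), `fluorescence`, `luminescence`,
#' and optionally `condition`, `well`, `time_min`. Returns a titration
#' tibble with the computed `bret` ratio in mBU.
#'
#' @param path CSV path.
#' @param f_background,l_background Background readings.
#' @return A `bret_titration` tibble.
#' @export
read_bret_plate <- function(path, f_background = 0, l_background = 0) {
  df <- as_tibble(read.csv(path))
  need <- c("x", "fluorescence", "luminescence")
  if (!all(need %in% names(df))) {
    abort(paste0("Plate CSV needs columns: ", paste(need, collapse = ", ")))
  }
  df$bret <- bret_ratio(df$fluorescence, df$luminescence,
                        f_background, l_background)
  class(df) <- c("bret_titration", class(df))
  df
}
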