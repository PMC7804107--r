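#' Parameters for the secretion-chip simulator
#'
#' Emulates a microwell antibody-barcode secretion assay: Poisson cell
#' loading (a majority of wells stay empty at the default loading),
#' smooth spatial background drift over the array, Gaussian well noise,
#' and planted secretor profiles among cell-containing wells. Pairs of
#' analytes listed in `exclusivity_pairs` must never co-occur within a
#' profile, planting (near-)mutually exclusive secretion.
#'
#' @param grid_shape Integer (rows, cols); `n_wells = rows * cols`.
#' @param n_wells Total wells; must equal `prod(grid_shape)`.
#' @param mean_cells_per_well Poisson loading rate (default 0.5: ~61% of
#'   wells are zero-cell).
#' @param analytes Analyte names.
#' @param background_drift_amplitude Peak-to-trough amplitude (a.f.u.) of
#'   the smooth drift surface.
#' @param background_noise_sd Gaussian well-to-well noise SD (a.f.u.).
#' @param secretor_profiles Data frame with columns `profile`, `fraction`
#'   and one mean-intensity column (a.f.u.) per analyte. Fractions are
#'   the mixing proportions among cell-containing wells and must sum to
#'   <= 1; the remainder are silent cells.
#' @param signal_cv Coefficient of variation of the per-well secretion
#'   signal around its profile mean.
#' @param exclusivity_pairs List of length-2 character vectors of
#'   analytes that no single profile may co-secrete.
#' @param seed Integer seed.
#' @return A validated `chip_sim_params` list.
#' @export
chip_sim_params <- function(grid_shape = c(50L, 40L),
                            n_wells = prod(grid_shape),
                            mean_cells_per_well = 0.5,
                            analytes = c("TNF", "CCL5", "IL6", "IL12p40", "Chi3l3"),
                            background_drift_amplitude = 100,
                            background_noise_sd = 20,
                            secretor_profiles = default_secretor_profiles(analytes),
                            signal_cv = 0.15,
                            exclusivity_pairs = list(c("IL6", "Chi3l3")),
                            seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 1L)) {
    abort("`grid_shape` must be two positive integers (rows, cols).")
  }
  if (n_wells != prod(grid_shape)) {
    abort(sprintf("`n_wells` (%d) must equal rows * cols (%d).",
                  n_wells, prod(grid_shape)))
  }
  if (mean_cells_per_well < 0) abort("`mean_cells_per_well` must be >= 0.")
  if (background_drift_amplitude < 0 || background_noise_sd < 0) {
    abort("Background amplitudes must be non-negative.")
  }
  prof <- as_tibble(secretor_profiles)
  if (nrow(prof)) {
    if (!all(c("profile", "fraction") %in% names(prof)) ||
        !all(analytes %in% names(prof))) {
      abort("`secretor_profiles` needs columns profile, fraction and one per analyte.")
    }
    if (any(prof$fraction < 0) || sum(prof$fraction) > 1 + 1e-9) {
      abort("Profile fractions must be non-negative and sum to <= 1.")
    }
    if (any(as.matrix(prof[, analytes]) < 0)) {
      abort("Profile signal means must be non-negative.")
    }
    for (pr in exclusivity_pairs) {
      both <- prof[[pr[1]]] > 0 & prof[[pr[2]]] > 0
      if (any(both)) {
        abort(sprintf("Profiles %s co-secrete the exclusive pair (%s, %s).",
                      paste(prof$profile[both], collapse = ", "), pr[1], pr[2]))
      }
    }
  }
  structure(list(grid_shape = grid_shape, n_wells = as.integer(n_wells),
                 mean_cells_per_well = mean_cells_per_well,
                 analytes = analytes,
                 background_drift_amplitude = background_drift_amplitude,
                 background_noise_sd = background_noise_sd,
                 secretor_profiles = prof, signal_cv = signal_cv,
                 exclusivity_pairs = exclusivity_pairs,
                 seed = as.integer(seed)),
            class = "chip_sim_params")
}

#' Default planted secretor profiles
#'
#' Five profiles over the default five-analyte panel: three inflammatory
#' (A-type) profiles secreting TNF/CCL5/IL6/IL12p40 combinations, one
#' resolving (B-type) profile secreting Chi3l3, and one mixed profile
#' secreting TNF with Chi3l3. IL6 and Chi3l3 never co-occur, planting the
#' mutually exclusive pair.
#'
#' @param analytes The five default analyte names.
#' @return Tibble usable as `secretor_profiles`.
#' @export
default_secretor_profiles <- function(analytes = c("TNF", "CCL5", "IL6",
                                                   "IL12p40", "Chi3l3")) {
  prof <- tibble(
    profile = c("A_inflammatory", "A_secondary", "A_tnf_only",
                "B_resolving", "mixed"),
    fraction = c(0.20, 0.15, 0.10, 0.20, 0.05),
    TNF = c(800, 0, 600, 0, 500),
    CCL5 = c(600, 400, 0, 0, 0),
    IL6 = c(0, 700, 0, 0, 0),
    IL12p40 = c(500, 600, 0, 0, 0),
    Chi3l3 = c(0, 0, 0, 900, 700))
  names(prof)[3:7] <- analytes
  prof
}

# Smooth separable low-order polynomial drift surface, peak `amplitude`.
drift_surface <- function(row, col, rows, cols, amplitude) {
  rn <- if (rows > 1L) (row - 1) / (rows - 1) else rep(0, length(row))
  cn <- if (cols > 1L) (col - 1) / (cols - 1) else rep(0, length(col))
  amplitude * (0.4 * rn + 0.3 * cn^2 + 0.3 * rn * cn)
}

#' Simulate a planted-truth secretion chip
#'
#' Wells are loaded with Poisson(`mean_cells_per_well`) cells. Wells with
#' at least one cell are assigned a secretor profile with the configured
#' mixing fractions (remainder silent). Raw intensity = smooth drift +
#' Gaussian noise + (for secretors) a signal drawn around the profile
#' mean with CV `signal_cv`, truncated at 0.
#'
#' @param params A [chip_sim_params()].
#' @return List with `chip` (a raw [secretion_chip()]) and `truth`, a
#'   tibble (well_id, cell_count, profile) where profile is `"empty"`,
#'   `"silent"`, or a planted profile name.
#' @export
simulate_chip <- function(params) {
  stopifnot(inherits(params, "chip_sim_params"))
  p <- params
  rows <- p$grid_shape[1]; cols <- p$grid_shape[2]
  grid <- expand.grid(col = seq_len(cols), row = seq_len(rows))[, c("row", "col")]
  n <- p$n_wells
  well_id <- sprintf("well%0*d", nchar(n), seq_len(n))
  prof <- p$secretor_profiles
  out <- withr::with_seed(p$seed, {
    cell_count <- rpois(n, p$mean_cells_per_well)
    profile <- rep("empty", n)
    loaded <- which(cell_count > 0)
    if (length(loaded) && nrow(prof)) {
      pick <- sample(c(prof$profile, "silent"), length(loaded), replace = TRUE,
                     prob = c(prof$fraction, max(0, 1 - sum(prof$fraction))))
      profile[loaded] <- pick
    } else if (length(loaded)) {
      profile[loaded] <- "silent"
    }
    drift <- drift_surface(grid$row, grid$col, rows, cols,
                           p$background_drift_amplitude)
    intens <- matrix(0, n, length(p$analytes),
                     dimnames = list(well_id, p$analytes))
    for (j in seq_along(p$analytes)) {
      noise <- if (p$background_noise_sd > 0) {
        rnorm(n, 0, p$background_noise_sd)
      } else rep(0, n)
      intens[, j] <- drift + noise
    }
    for (k in seq_len(nrow(prof))) {
      wells_k <- which(profile == prof$profile[k])
      if (!length(wells_k)) next
      for (j in seq_along(p$analytes)) {
        mu <- prof[[p$analytes[j]]][k]
        if (mu > 0) {
          sig <- rnorm(length(wells_k), mu, p$signal_cv * mu)
          intens[wells_k, j] <- intens[wells_k, j] + pmax(sig, 0)
        }
      }
    }
    list(cell_count = cell_count, profile = profile, intens = intens)
  })
  wells <- tibble(well_id = well_id, row = grid$row, col = grid$col,
                  cell_count = out$cell_count)
  for (a in p$analytes) wells[[a]] <- out$intens[, a]
  list(chip = secretion_chip(wells, p$analytes),
       truth = tibble(well_id = well_id, cell_count = out$cell_count,
                      profile = ifelse(out$cell_count == 0, "empty",
                                       out$profile)))
}
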