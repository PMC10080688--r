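# Plain-text readers/writers for the pipeline's interchange formats:
# protonation trajectories, energy series, transition-charge sets (XYZ +
# charge CSV), and feature matrices with provenance columns.

#' Write a protonation trajectory to CSV
#'
#' Header comment line `# pH=<v> seed=<v> dt_ps=<v>`, then columns
#' `frame,time_ps,<site...>` with 0/1 entries.
#'
#' @param traj A `protonation_trajectory`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_protonation_csv <- function(traj, path) {
  stopifnot(inherits(traj, "protonation_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pH=%.6g seed=%d dt_ps=%.6g",
                     traj$pH, traj$seed, traj$dt_ps), con)
  df <- data.frame(frame = seq_len(nrow(traj$states)),
                   time_ps = seq_len(nrow(traj$states)) * traj$dt_ps,
                   traj$states, check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a protonation trajectory from CSV
#'
#' @param path File written by [write_protonation_csv()].
#' @return A `protonation_trajectory`.
#' @export
read_protonation_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- c(pH = NA_real_, seed = NA_real_, dt_ps = NA_real_)
  if (startsWith(hdr, "#")) {
    for (kv in strsplit(sub("^#\\s*", "", hdr), "\\s+")[[1L]]) {
      parts <- strsplit(kv, "=", fixed = TRUE)[[1L]]
      if (parts[1L] %in% names(meta)) meta[parts[1L]] <- as.numeric(parts[2L])
    }
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  sites <- setdiff(names(df), c("frame", "time_ps"))
  states <- as.matrix(df[, sites, drop = FALSE])
  storage.mode(states) <- "integer"
  structure(list(pH = meta[["pH"]], dt_ps = meta[["dt_ps"]], sites = sites,
                 states = states, seed = as.integer(meta[["seed"]])),
            class = "protonation_trajectory")
}

#' Write an energy series to CSV (`index,energy_cm1`)
#'
#' @param series An `energy_series`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_energy_csv <- function(series, path) {
  stopifnot(inherits(series, "energy_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# state=%s seed=%d", series$state_label, series$seed), con)
  utils::write.csv(data.frame(index = seq_along(series$values),
                              energy_cm1 = series$values),
                   con, row.names = FALSE)
  invisible(path)
}

#' Read an energy series from CSV
#'
#' @param path File written by [write_energy_csv()].
#' @return An `energy_series`.
#' @export
read_energy_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  state <- "LE"; seed <- NA_integer_
  if (startsWith(hdr, "#")) {
    for (kv in strsplit(sub("^#\\s*", "", hdr), "\\s+")[[1L]]) {
      parts <- strsplit(kv, "=", fixed = TRUE)[[1L]]
      if (parts[1L] == "state") state <- parts[2L]
      if (parts[1L] == "seed") seed <- as.integer(parts[2L])
    }
  }
  df <- utils::read.csv(path, comment.char = "#")
  structure(list(state_label = state, values = df$energy_cm1, seed = seed),
            class = "energy_series")
}

#' Write a transition-charge set as CSV (`atom,x,y,z,q`)
#'
#' @param set A `transition_charge_set`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_charge_csv <- function(set, path) {
  stopifnot(inherits(set, "transition_charge_set"))
  utils::write.csv(set$atoms, path, row.names = FALSE)
  invisible(path)
}

#' Read a transition-charge set from CSV
#'
#' @param path CSV with columns `atom,x,y,z,q`.
#' @param pigment_id,state_label Labels for the returned set.
#' @return A `transition_charge_set`.
#' @export
read_charge_csv <- function(path, pigment_id = basename(path),
                            state_label = "") {
  transition_charge_set(pigment_id, utils::read.csv(path), state_label)
}

#' Read an XYZ coordinate file
#'
#' @param path Standard XYZ: atom count, comment, then `element x y z`.
#' @return Data frame with `atom`, `x`, `y`, `z` (Angstrom).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  rows <- strsplit(trimws(lines[3L:(2L + n)]), "\\s+")
  data.frame(atom = vapply(rows, `[[`, character(1L), 1L),
             x = as.numeric(vapply(rows, `[[`, character(1L), 2L)),
             y = as.numeric(vapply(rows, `[[`, character(1L), 3L)),
             z = as.numeric(vapply(rows, `[[`, character(1L), 4L)))
}

#' Write an XYZ coordinate file
#'
#' @param atoms Data frame with `atom`, `x`, `y`, `z`.
#' @param path Output file.
#' @param comment Second-line comment.
#' @return Invisibly, `path`.
#' @export
write_xyz <- function(atoms, path, comment = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(nrow(atoms)), comment), con)
  writeLines(sprintf("%s %.6f %.6f %.6f", atoms$atom, atoms$x, atoms$y,
                     atoms$z), con)
  invisible(path)
}

#' Published reference energetics of the LHCSR1 L1 dimer
#'
#' Cluster-averaged vertical energies of the locally excited (Chl Qy) and
#' charge-transfer (Lut+Chl-) states and their couplings for the two main
#' conformational clusters of the L1-Lut/Chl a612 pair of LHCSR1, with 95%
#' confidence intervals (cm^-1), as established by polarizable-embedding
#' QM/MM cluster analyses. Used as the fixed reference input for the
#' gap and rate-ratio calculations.
#'
#' @return Data frame with columns `cluster`, `E_LE_cm1`, `E_LE_ci95`,
#'   `E_CT_cm1`, `E_CT_ci95`, `V_cm1`, `V_ci95`.
#' @export
l1_dimer_reference <- function() {
  path <- system.file("extdata", "l1_dimer_reference.csv",
                      package = "phquench", mustWork = TRUE)
  utils::read.csv(path)
}
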