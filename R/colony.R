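#' Colony fitness from lineage labels
#'
#' Colony fitness is the total biomass, at simulation end, of all
#' descendants of one founder cell. Lineage labels (`founder_id`) are
#' carried through every division, so fitness is a per-founder sum of final
#' cell masses; the per-colony values partition the simulation's final
#' biomass exactly.
#'
#' @param final_cells cell table at simulation end.
#' @param founders initial cell table (one row per founder).
#' @return Named numeric vector of fitness (fg), one per founder, in
#'   founder order. Founders with no descendants (impossible without cell
#'   death, hence flagged) get 0 with a warning.
#' @examples
#' sim_cells <- data.frame(id = 1:3, species = "heterotroph",
#'                         founder_id = c(1, 1, 2), x = 0, y = 0, z = 0,
#'                         mass = c(10, 20, 5), diameter = 1, birth_time = 0)
#' founders <- sim_cells[1:2, ]
#' colony_fitness(sim_cells, founders)
#' @export
colony_fitness <- function(final_cells, founders) {
  orphan <- setdiff(final_cells$founder_id, founders$founder_id)
  if (length(orphan)) {
    stop("final cells carry founder_id(s) absent from the founder table: ",
         paste(orphan, collapse = ", "))
  }
  s <- rowsum(final_cells$mass, final_cells$founder_id)
  fit <- stats::setNames(rep(0, nrow(founders)),
                         as.character(founders$founder_id))
  fit[rownames(s)] <- s
  if (any(fit == 0)) {
    warning("founder(s) with zero descendants: ",
            paste(names(fit)[fit == 0], collapse = ", "), call. = FALSE)
  }
  fit
}

#' Run a batch of randomly seeded simulations
#'
#' Reproduces the fitness-prediction study design: each simulation is
#' seeded with 1-100 cells of each species, uniformly random positions and
#' sizes, and a random inducer level, then run to the stop rule. Seeds for
#' the individual runs are derived deterministically from `seed`.
#'
#' @param n_sims number of simulations.
#' @param seed master RNG seed.
#' @param config a [simulation_config()] shared by all runs.
#' @param params parameter list.
#' @param n_range inclusive range for per-species founder counts.
#' @param iptg_range range of the uniformly drawn inducer level, mM.
#' @param progress print a dot per completed run.
#' @return List of `consortium_sim` objects, class `colony_batch`.
#' @export
run_colony_batch <- function(n_sims, seed = 1,
                             config = simulation_config(),
                             params = default_params(),
                             n_range = c(1, 100), iptg_range = c(0, 1),
                             progress = FALSE) {
  stopifnot(n_sims >= 1)
  set.seed(seed)
  n_c <- sample(n_range[1]:n_range[2], n_sims, replace = TRUE)
  n_h <- sample(n_range[1]:n_range[2], n_sims, replace = TRUE)
  iptg <- stats::runif(n_sims, iptg_range[1], iptg_range[2])
  run_seeds <- sample.int(.Machine$integer.max, n_sims)
  sims <- vector("list", n_sims)
  for (i in seq_len(n_sims)) {
    sp <- seed_spec(n_c[i], n_h[i], iptg = iptg[i], rng_seed = run_seeds[i],
                    domain = config$domain)
    sims[[i]] <- simulate_consortium(config, sp, params)
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  structure(sims, class = "colony_batch")
}

#' Assemble the regression feature table for a simulation batch
#'
#' One row per colony: the t = 0 spatial features of its founder
#' ([colony_features()]) plus the fitness target ([colony_fitness()]).
#' Rows with undefined (NA) metrics - e.g. species-specific distances when
#' one species has a single colony - are dropped, and the count of dropped
#' rows is recorded in the `n_dropped` attribute.
#'
#' @param batch a list of `consortium_sim` objects (e.g. from
#'   [run_colony_batch()]).
#' @return data.frame with the [colony_features()] columns plus `sim` (run
#'   index) and `fitness` (fg); attribute `n_dropped`.
#' @export
build_feature_table <- function(batch) {
  if (length(batch) == 0) stop("empty simulation batch")
  rows <- vector("list", length(batch))
  for (i in seq_along(batch)) {
    sim <- batch[[i]]
    layout <- colony_layout(sim$cells_initial, sim$config$domain)
    feats <- colony_features(layout, iptg = sim$iptg, params = sim$params)
    feats$fitness <- as.numeric(colony_fitness(sim$cells_final,
                                               sim$cells_initial))
    feats$sim <- i
    rows[[i]] <- feats
  }
  tab <- do.call(rbind, rows)
  keep <- stats::complete.cases(tab)
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Write/read the feature table as CSV
#'
#' Plain CSV with a one-line schema-version header comment; the reader
#' checks the header and round-trips the table exactly.
#'
#' @param table feature table from [build_feature_table()].
#' @param path file path.
#' @return `path` invisibly, or the read table.
#' @export
write_feature_table <- function(table, path) {
  con <- file(path, "w")
  writeLines("# consortsim feature table v1", con)
  utils::write.csv(table, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!grepl("consortsim feature table v1", hdr, fixed = TRUE)) {
    stop("not a consortsim feature table (missing schema header)")
  }
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
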