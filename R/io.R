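#' Write a topology (and optional frustration set) to JSON
#'
#' Serialises everything a simulation needs -- native geometry, contacts
#' with r0 and MJ weights, frustration pairs -- so runs are reproducible
#' without re-parsing the source PDB.
#'
#' @param topo A `cg_topology`.
#' @param path Output path (JSON).
#' @param fset Optional `cg_frustration`.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topo, path, fset = NULL) {
  obj <- list(format = "frustfold-topology-v1",
              n = topo$n,
              sequence = topo$sequence,
              ca0 = unclass(topo$ca0),
              r0 = topo$r0, theta0 = topo$theta0, phi0 = topo$phi0,
              cutoff = topo$cutoff, min_separation = topo$min_separation,
              contacts = as.list(topo$contacts))
  if (!is.null(fset))
    obj$frustration <- list(pairs = as.list(fset$pairs),
                            hydrophobic_index = fset$hydrophobic_index)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a topology written by [write_topology()]
#'
#' @param path JSON path.
#' @return List with `topology` (`cg_topology`) and `frustration`
#'   (`cg_frustration` or `NULL`).
#' @export
read_topology <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "frustfold-topology-v1"))
    stop("input error: not a frustfold topology file", call. = FALSE)
  topo <- structure(list(n = obj$n, ca0 = matrix(obj$ca0, ncol = 3),
                         r0 = obj$r0, theta0 = obj$theta0, phi0 = obj$phi0,
                         contacts = tibble::as_tibble(obj$contacts),
                         sequence = obj$sequence,
                         min_separation = as.integer(obj$min_separation),
                         cutoff = obj$cutoff),
                    class = "cg_topology")
  fset <- NULL
  if (!is.null(obj$frustration))
    fset <- structure(list(pairs = tibble::as_tibble(obj$frustration$pairs),
                           hydrophobic_index = obj$frustration$hydrophobic_index),
                      class = "cg_frustration")
  list(topology = topo, frustration = fset)
}

#' Export a trajectory's C-alpha trace as a multi-model PDB
#'
#' @param traj A `cg_trajectory`.
#' @param path Output path.
#' @param every Write every `every`-th snapshot.
#' @return `path`, invisibly.
#' @export
write_pdb_trajectory <- function(traj, path, every = 10L) {
  sel <- seq(1, length(traj$step), by = every)
  con <- file(path, "w")
  on.exit(close(con))
  n <- dim(traj$coords)[2]
  for (mi in seq_along(sel)) {
    s <- sel[mi]
    writeLines(sprintf("MODEL %8d", mi), con)
    writeLines(sprintf(
      "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(n), seq_len(n),
      traj$coords[s, , 1], traj$coords[s, , 2], traj$coords[s, , 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
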