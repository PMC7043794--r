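#' Read a connectivity matrix from delimited text
#'
#' Fixed dialect: comma separator, no header, '.' decimal, row \code{i} =
#' postsynaptic unit \code{i}. The file must be rectangular, square and
#' fully numeric (no NA/NaN); violations raise descriptive parse errors with
#' the offending row/column.
#'
#' @param path file path.
#' @param label provenance label (defaults to the file path).
#' @return A \code{network_model}.
#' @export
read_network <- function(path, label = path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty matrix file: ", path)
  rows <- strsplit(lines, ",", fixed = TRUE)
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1)
    stop(sprintf("ragged input in %s: row %d has %d fields, row 1 has %d",
                 path, which(ncols != ncols[1])[1],
                 ncols[which(ncols != ncols[1])[1]], ncols[1]))
  n <- length(rows)
  if (ncols[1] != n)
    stop(sprintf("non-square matrix in %s: %d rows x %d columns",
                 path, n, ncols[1]))
  J <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    vals <- suppressWarnings(as.numeric(rows[[i]]))
    bad <- which(!is.finite(vals))
    if (length(bad))
      stop(sprintf("non-numeric or non-finite entry '%s' at row %d, column %d of %s",
                   trimws(rows[[i]][bad[1]]), i, bad[1], path))
    J[i, ] <- vals
  }
  network_model(J, label = label)
}

#' Write a connectivity matrix as delimited text
#'
#' Inverse of [read_network()]: 17 significant digits, so a write/read
#' round-trip reproduces the matrix bit-faithfully.
#'
#' @param net a \code{network_model} (or bare square matrix).
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
write_network <- function(net, path) {
  J <- as_network(net)$J
  writeLines(apply(J, 1, function(r)
    paste(sprintf("%.17g", r), collapse = ",")), path)
  invisible(path)
}

#' Export a trajectory and its norm time course
#'
#' Writes the state trajectory as CSV with header
#' \code{time,unit_1,...,unit_N} and a companion \code{time,norm} file.
#'
#' @param traj a \code{trajectory_record}.
#' @param path states CSV path.
#' @param norm_path norms CSV path (default: \code{path} with a
#'   \code{_norm} suffix before the extension).
#' @return Character vector of the two paths, invisibly.
#' @export
write_trajectory <- function(traj, path,
                             norm_path = sub("(\\.[^.]*)?$", "_norm\\1", path)) {
  stopifnot(inherits(traj, "trajectory_record"))
  df <- data.frame(time = traj$times, traj$states)
  names(df) <- c("time", paste0("unit_", seq_len(ncol(traj$states))))
  utils::write.csv(df, path, row.names = FALSE)
  utils::write.csv(data.frame(time = traj$times, norm = traj$norms),
                   norm_path, row.names = FALSE)
  invisible(c(path, norm_path))
}

#' Export singular value trajectories
#'
#' CSV with header \code{time,sv_1,...,sv_N}.
#'
#' @param grid an \code{sv_trajectory_grid}.
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
write_sv_grid <- function(grid, path) {
  stopifnot(inherits(grid, "sv_trajectory_grid"))
  df <- data.frame(time = grid$times, t(grid$singvals))
  names(df) <- c("time", paste0("sv_", seq_len(nrow(grid$singvals))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a spectral summary as JSON
#'
#' @param summ a \code{spectral_summary}.
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
write_spectral_summary <- function(summ, path) {
  stopifnot(inherits(summ, "spectral_summary"))
  out <- list(regime = summ$regime,
              spectral_abscissa = summ$spectral_abscissa,
              lambda_max_sym = summ$lambda_max_sym,
              n_amplified = summ$n_amplified,
              margin = summ$margin,
              eigs_full_re = Re(summ$eigs_full),
              eigs_full_im = Im(summ$eigs_full),
              eigs_sym = summ$eigs_sym)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export amplified channels as JSON
#'
#' @param ch an \code{amplified_channels} object.
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
write_channels <- function(ch, path) {
  stopifnot(inherits(ch, "amplified_channels"))
  out <- list(t_star = ch$t_star, margin = ch$margin,
              n_channels = length(ch$sigma),
              channels = lapply(seq_along(ch$sigma), function(k)
                list(sigma = ch$sigma[k],
                     input = ch$inputs[, k],
                     readout = ch$readouts[, k])))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Generate reference fixtures on disk
#'
#' Writes a deterministic connectivity matrix (CSV) and its configuration
#' (JSON) for the built-in ensembles, reproducing the standard study
#' settings of each family.
#'
#' @param kind one of \code{"gaussian"}, \code{"twopop"}, \code{"ei"},
#'   \code{"rank1"}, \code{"rankP"}.
#' @param params named list of ensemble parameters: \code{gaussian} takes
#'   \code{g, N}; \code{twopop} takes \code{trace, det, Delta} (or
#'   \code{a, b, c, d}); \code{ei} takes \code{w, k}; \code{rank1} takes
#'   \code{N, Delta, rho, mode}; \code{rankP} additionally \code{P}.
#' @param seed RNG seed (recorded in the config).
#' @param dir output directory (created if missing).
#' @return Named character vector with the \code{matrix} and \code{config}
#'   paths.
#' @export
fixture_generator <- function(kind, params = list(), seed = 1,
                              dir = tempdir()) {
  kinds <- c("gaussian", "twopop", "ei", "rank1", "rankP")
  if (!kind %in% kinds)
    stop("unknown fixture kind '", kind, "'; expected one of: ",
         paste(kinds, collapse = ", "))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  net <- switch(kind,
    gaussian = gaussian_network(params$g, params$N, seed = seed),
    twopop = {
      p <- if (!is.null(params$a))
        two_pop(params$a, params$b, params$c, params$d)
      else
        two_pop_from_spectrum(params$trace, params$det,
                              Delta = params$Delta %||% 0)
      network_model(p$J, label = "twopop")
    },
    ei = network_model(ei_twopop(params$w, params$k)$J, label = "ei"),
    rank1 = lowrank_network(lowrank_spec(params$N, params$Delta,
                                         rho = params$rho %||% 0, P = 1,
                                         seed = seed,
                                         mode = params$mode %||% "sampled")),
    rankP = lowrank_network(lowrank_spec(params$N, params$Delta,
                                         rho = params$rho %||% 0,
                                         P = params$P, seed = seed,
                                         mode = params$mode %||% "sampled")))
  mpath <- file.path(dir, paste0(kind, "_matrix.csv"))
  cpath <- file.path(dir, paste0(kind, "_config.json"))
  write_network(net, mpath)
  jsonlite::write_json(c(list(kind = kind, seed = seed, label = net$label),
                         params),
                       cpath, auto_unbox = TRUE, digits = NA)
  c(matrix = mpath, config = cpath)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
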