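# Rotamer extraction and sequence-dependent rotamer library construction.

#' Boltzmann equilibrium populations from free energies
#'
#' Probabilities proportional to `exp(-F / kB T)`, normalized to sum to
#' one.  Invariant to adding a constant to all free energies.
#'
#' @param free_energies Numeric vector, kcal/mol.
#' @param temperature Temperature in Kelvin (default 298).
#' @return Numeric vector of probabilities summing to 1.
#' @export
equilibrium_populations <- function(free_energies, temperature = 298) {
  if (length(free_energies) == 0L) stop("empty free-energy list")
  if (any(!is.finite(free_energies))) stop("free energies must be finite")
  if (temperature <= 0) stop("temperature must be positive")
  w <- exp(-(free_energies - min(free_energies)) / (.kB * temperature))
  w / sum(w)
}

#' Context key helpers
#'
#' A sequence context is the triple (previous, central, next) of
#' three-letter residue codes, serialized as "PREV-CENT-NEXT".
#' @keywords internal
context_key <- function(prev, central, nxt) paste(prev, central, nxt, sep = "-")

split_context <- function(key) {
  parts <- strsplit(key, "-", fixed = TRUE)[[1L]]
  if (length(parts) != 3L) stop("malformed context key: ", key)
  parts
}

#' A conformational ensemble for one sequence context
#'
#' @param torsions Matrix (m conformations x n chi) of chi angles in
#'   degrees, or a list of equal-length vectors.
#' @param free_energy Numeric vector of per-conformation free energies
#'   (kcal/mol), length m.
#' @param potential_energy Optional per-conformation potential energies.
#' @param ids Optional conformation identifiers.
#' @return An object of class `"conformation_ensemble"`.
#' @export
conformation_ensemble <- function(torsions, free_energy,
                                  potential_energy = NULL, ids = NULL) {
  x <- .as_torsion_matrix(torsions)
  x[] <- normalize_angle(x)
  m <- nrow(x)
  if (length(free_energy) != m) stop("one free energy per conformation required")
  if (any(!is.finite(free_energy))) stop("free energies must be finite")
  if (is.null(ids)) ids <- seq_len(m)
  structure(list(torsions = x, free_energy = as.numeric(free_energy),
                 potential_energy = potential_energy, ids = ids),
            class = "conformation_ensemble")
}

#' Summarize one cluster of conformations as a rotamer
#'
#' The rotamer mean is the per-chi circular mean over member
#' conformations and the spread the per-chi circular population standard
#' deviation; clusters with a single member are assigned a standard
#' deviation of 1.0 degrees for every chi, representing the residual
#' variance of displacements about the underlying minimum.  The rotamer
#' probability is the sum of the member occupation probabilities.
#'
#' @param torsions Matrix of member chi angles (members x n chi).
#' @param populations Occupation probability of each member.
#' @param context Optional context key "PREV-CENT-NEXT".
#' @return A list with `chi_mean`, `chi_sd`, `probability`,
#'   `member_count` and `context`.
#' @export
cluster_to_rotamer <- function(torsions, populations, context = NA_character_) {
  x <- .as_torsion_matrix(torsions)
  m <- nrow(x)
  if (m == 0L) stop("empty cluster")
  if (length(populations) != m) stop("one population per member required")
  chi_mean <- apply(x, 2L, circular_mean)
  chi_sd <- if (m == 1L) rep(1.0, ncol(x)) else apply(x, 2L, circular_sd)
  list(chi_mean = chi_mean, chi_sd = chi_sd,
       probability = sum(populations), member_count = m, context = context)
}

#' Build a sequence-dependent rotamer library
#'
#' The fitting routine of the package.  For every sequence context the
#' conformations are assigned Boltzmann occupation probabilities at
#' `temperature`, clustered by average linkage in torsional space under
#' the periodic metric, each flat cluster (cut at `cutoff` degrees) is
#' summarized as a rotamer via [cluster_to_rotamer()], and rotamers with
#' occupation probability strictly below `prune` are removed.  Retained
#' probabilities are not renormalized; move generation renormalizes at
#' draw time.
#'
#' @param ensembles Named list of [conformation_ensemble()] objects,
#'   keyed by context "PREV-CENT-NEXT".
#' @param cutoff Flat-cluster cut in degrees (default 40).
#' @param temperature Temperature for occupation probabilities, Kelvin
#'   (default 298).
#' @param prune Minimum retained occupation probability (default 0.005);
#'   rotamers with probability strictly less than this are dropped.
#' @return An object of class `"rotamer_library"`: list with `entries`
#'   (one data-frame row per rotamer: `prev`, `central`, `nxt`, `n_chi`,
#'   `chi1_mean`..`chi4_mean`, `chi1_sd`..`chi4_sd`, `probability`,
#'   `member_count`) sorted by context then descending probability, and
#'   `metadata`.
#' @export
rotamer_library <- function(ensembles, cutoff = 40, temperature = 298,
                            prune = 0.005) {
  if (length(ensembles) == 0L) stop("no ensembles supplied")
  if (is.null(names(ensembles)) || any(names(ensembles) == ""))
    stop("ensembles must be named by context \"PREV-CENT-NEXT\"")
  rows <- list()
  for (key in names(ensembles)) {
    ctx <- split_context(key)
    known <- sidechain_chi_count(ctx[2L])
    ens <- ensembles[[key]]
    stopifnot(inherits(ens, "conformation_ensemble"))
    n_chi <- ncol(ens$torsions)
    if (known == 0L && ctx[2L] %in% c("ALA", "GLY"))
      stop("central residue ", ctx[2L], " in context ", key,
           " has no chi dihedrals")
    if (known > 0L && n_chi != known)
      stop("context ", key, ": expected ", known, " chi dihedrals, got ", n_chi)
    if (n_chi < 1L || n_chi > 4L)
      stop("context ", key, ": chi dimension must be between 1 and 4")
    pops <- equilibrium_populations(ens$free_energy, temperature)
    cl <- average_linkage_cluster(pairwise_torsion_distances(ens$torsions),
                                  cutoff = cutoff)
    for (g in seq_len(cl$k)) {
      idx <- which(cl$labels == g)
      rot <- cluster_to_rotamer(ens$torsions[idx, , drop = FALSE],
                                pops[idx], context = key)
      if (rot$probability < prune) next
      cm <- cs <- rep(NA_real_, 4L)
      cm[seq_len(n_chi)] <- rot$chi_mean
      cs[seq_len(n_chi)] <- rot$chi_sd
      rows[[length(rows) + 1L]] <-
        data.frame(prev = ctx[1L], central = ctx[2L], nxt = ctx[3L],
                   n_chi = n_chi,
                   chi1_mean = cm[1L], chi2_mean = cm[2L],
                   chi3_mean = cm[3L], chi4_mean = cm[4L],
                   chi1_sd = cs[1L], chi2_sd = cs[2L],
                   chi3_sd = cs[3L], chi4_sd = cs[4L],
                   probability = rot$probability,
                   member_count = rot$member_count,
                   stringsAsFactors = FALSE)
    }
  }
  entries <- do.call(rbind, rows)
  if (is.null(entries))
    entries <- utils::read.table(text = "", col.names = .library_columns())
  key <- context_key(entries$prev, entries$central, entries$nxt)
  entries <- entries[order(key, -entries$probability), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(entries = entries,
                 metadata = list(temperature = temperature, cutoff = cutoff,
                                 prune = prune, format_version = 1L)),
            class = "rotamer_library")
}

.library_columns <- function() {
  c("prev", "central", "nxt", "n_chi",
    "chi1_mean", "chi2_mean", "chi3_mean", "chi4_mean",
    "chi1_sd", "chi2_sd", "chi3_sd", "chi4_sd",
    "probability", "member_count")
}

#' Rotamers of one context
#'
#' Looks up the library entries for a context key.  Generic "HIS"
#' central residues fall back to the delta-protonated state (HID) when
#' no generic entry exists.
#'
#' @param library A `"rotamer_library"`.
#' @param context Context key "PREV-CENT-NEXT".
#' @return Data frame of entries (possibly zero rows).
#' @export
library_context <- function(library, context) {
  stopifnot(inherits(library, "rotamer_library"))
  e <- library$entries
  ctx <- split_context(context)
  sel <- e$prev == ctx[1L] & e$central == ctx[2L] & e$nxt == ctx[3L]
  if (!any(sel) && toupper(ctx[2L]) == "HIS")
    sel <- e$prev == ctx[1L] & e$central == "HID" & e$nxt == ctx[3L]
  e[sel, , drop = FALSE]
}

.chi_mean_matrix <- function(entries) {
  as.matrix(entries[, c("chi1_mean", "chi2_mean", "chi3_mean", "chi4_mean")])
}

#' Match an observed side-chain conformation against rotamers
#'
#' A rotamer matches iff every per-chi periodic distance between the
#' observation and the rotamer mean is strictly less than `tol` degrees
#' (40 by default).  With `aggregate = TRUE` the criterion is instead
#' the aggregate torsional-space Euclidean distance being below `tol`.
#' Among multiple matches the highest-probability rotamer is returned.
#'
#' @param observed Numeric vector of chi angles in degrees.
#' @param candidates Data frame of library entries (e.g. from
#'   [library_context()]).
#' @param tol Matching tolerance in degrees (default 40).
#' @param aggregate Use the aggregate Euclidean criterion instead of the
#'   per-chi criterion (default FALSE).
#' @return The matching entry (one-row data frame), or `NULL`.
#' @export
match_sidechain <- function(observed, candidates, tol = 40, aggregate = FALSE) {
  if (nrow(candidates) == 0L) return(NULL)
  n <- length(observed)
  if (any(candidates$n_chi != n))
    stop("observed has ", n, " chi dihedrals but candidates have ",
         paste(unique(candidates$n_chi), collapse = ", "))
  cm <- .chi_mean_matrix(candidates)[, seq_len(n), drop = FALSE]
  d <- abs((sweep(cm, 2L, observed)) %% 360)
  d <- pmin(d, 360 - d)
  ok <- if (aggregate) sqrt(rowSums(d^2)) < tol else
    apply(d < tol, 1L, all)
  if (!any(ok)) return(NULL)
  hits <- candidates[ok, , drop = FALSE]
  hits[which.max(hits$probability), , drop = FALSE]
}

#' Distance from an observation to the nearest rotamer
#'
#' The minimum over candidate rotamers of the maximum per-chi periodic
#' distance to the rotamer mean.
#'
#' @inheritParams match_sidechain
#' @return Distance in degrees.
#' @export
nearest_distance <- function(observed, candidates) {
  if (nrow(candidates) == 0L) stop("no candidate rotamers")
  n <- length(observed)
  if (any(candidates$n_chi != n)) stop("chi dimension mismatch")
  cm <- .chi_mean_matrix(candidates)[, seq_len(n), drop = FALSE]
  d <- abs((sweep(cm, 2L, observed)) %% 360)
  d <- pmin(d, 360 - d)
  min(apply(d, 1L, max))
}

#' Coverage of observed side-chain conformations by a library
#'
#' For each observation the context is resolved in the library (with the
#' HIS -> HID fallback); unresolvable contexts are counted and excluded.
#' An observation is covered when [match_sidechain()] finds a rotamer
#' within the tolerance.  Reported per central residue type: the number
#' of observations, percent matched, and the mean rotamer count per
#' library context of that central residue (averaged uniformly over
#' contexts), plus an overall total.
#'
#' @param test_set Data frame with columns `prev`, `central`, `nxt` and
#'   `chi1`..`chi4` (NA for unused chi).
#' @param library A `"rotamer_library"`.
#' @param tol Matching tolerance in degrees (default 40).
#' @return A list with `by_residue` (data frame), `total_percent`, and
#'   `n_unresolved`.
#' @export
coverage_report <- function(test_set, library, tol = 40) {
  stopifnot(inherits(library, "rotamer_library"))
  if (nrow(test_set) == 0L) stop("empty test set")
  chi_cols <- paste0("chi", 1:4)
  matched <- central <- character(0)
  ok <- logical(0); n_unresolved <- 0L
  for (i in seq_len(nrow(test_set))) {
    row <- test_set[i, ]
    cand <- library_context(library, context_key(row$prev, row$central, row$nxt))
    if (nrow(cand) == 0L) { n_unresolved <- n_unresolved + 1L; next }
    obs <- as.numeric(row[chi_cols])[seq_len(cand$n_chi[1L])]
    central <- c(central, row$central)
    ok <- c(ok, !is.null(match_sidechain(obs, cand, tol = tol)))
  }
  if (length(ok) == 0L)
    return(list(by_residue = data.frame(), total_percent = NA_real_,
                n_unresolved = n_unresolved))
  e <- library$entries
  ctx_all <- context_key(e$prev, e$central, e$nxt)
  per_ctx <- tapply(ctx_all, e$central, function(k) mean(table(k)))
  res <- data.frame(central = sort(unique(central)), stringsAsFactors = FALSE)
  res$n <- as.integer(table(central)[res$central])
  res$n_matched <- as.integer(tapply(ok, central, sum)[res$central])
  res$percent <- 100 * res$n_matched / res$n
  res$mean_rotamers <- as.numeric(per_ctx[res$central])
  list(by_residue = res, total_percent = 100 * mean(ok),
       n_unresolved = n_unresolved)
}

#' Track a reference rotamer across sequence contexts
#'
#' Takes the highest-probability rotamer of the reference context
#' (typically the glycine-flanked tripeptide, whose neighbors place
#' minimal constraints on the central side chain) and, in every other
#' context with the same central residue, locates it by the matching
#' criterion and reports its occupation probability, 0 when absent.
#'
#' @param library A `"rotamer_library"`.
#' @param reference_context Context key, e.g. "GLY-SER-GLY".
#' @param tol Matching tolerance in degrees (default 40).
#' @param aggregate Use the aggregate Euclidean criterion (default
#'   FALSE, i.e. per-chi).
#' @return Named numeric vector of probabilities per context (the
#'   reference context included).
#' @export
reference_rotamer_tracking <- function(library, reference_context, tol = 40,
                                       aggregate = FALSE) {
  ref <- library_context(library, reference_context)
  if (nrow(ref) == 0L) stop("reference context ", reference_context,
                            " absent from library")
  ref <- ref[which.max(ref$probability), , drop = FALSE]
  n <- ref$n_chi[1L]
  ref_chi <- as.numeric(.chi_mean_matrix(ref))[seq_len(n)]
  e <- library$entries
  keys <- unique(context_key(e$prev, e$central, e$nxt)[e$central == ref$central])
  out <- vapply(keys, function(k) {
    hit <- match_sidechain(ref_chi, library_context(library, k),
                           tol = tol, aggregate = aggregate)
    if (is.null(hit)) 0 else hit$probability
  }, numeric(1L))
  names(out) <- keys
  out
}

#' @export
print.rotamer_library <- function(x, ...) {
  e <- x$entries
  cat("Sequence-dependent rotamer library\n")
  cat("  contexts:", length(unique(context_key(e$prev, e$central, e$nxt))),
      "  rotamers:", nrow(e), "\n")
  cat("  temperature:", x$metadata$temperature, "K",
      "  cutoff:", x$metadata$cutoff, "deg",
      "  prune: <", x$metadata$prune, "\n")
  invisible(x)
}

#' @export
summary.rotamer_library <- function(object, ...) {
  e <- object$entries
  ctx <- context_key(e$prev, e$central, e$nxt)
  s <- data.frame(central = sort(unique(e$central)), stringsAsFactors = FALSE)
  s$contexts <- as.integer(tapply(ctx, e$central, function(k) length(unique(k)))[s$central])
  s$rotamers <- as.integer(table(e$central)[s$central])
  s$mean_rotamers_per_context <- s$rotamers / s$contexts
  structure(list(by_residue = s, metadata = object$metadata),
            class = "summary.rotamer_library")
}

#' @export
print.summary.rotamer_library <- function(x, ...) {
  print(x$by_residue, row.names = FALSE)
  invisible(x)
}

#' Predict the rotamer assignment of observed side chains
#'
#' @param object A `"rotamer_library"`.
#' @param newdata Data frame with columns `prev`, `central`, `nxt`,
#'   `chi1`..`chi4`.
#' @param tol Matching tolerance in degrees.
#' @param ... Unused.
#' @return `newdata` with added columns `matched` (logical) and
#'   `probability` (of the matched rotamer, NA when unmatched).
#' @export
predict.rotamer_library <- function(object, newdata, tol = 40, ...) {
  chi_cols <- paste0("chi", 1:4)
  newdata$matched <- FALSE
  newdata$probability <- NA_real_
  for (i in seq_len(nrow(newdata))) {
    row <- newdata[i, ]
    cand <- library_context(object, context_key(row$prev, row$central, row$nxt))
    if (nrow(cand) == 0L) next
    obs <- as.numeric(row[chi_cols])[seq_len(cand$n_chi[1L])]
    hit <- match_sidechain(obs, cand, tol = tol)
    if (!is.null(hit)) {
      newdata$matched[i] <- TRUE
      newdata$probability[i] <- hit$probability
    }
  }
  newdata
}
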