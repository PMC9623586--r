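# TSV ensemble / test-set formats and programmatic fixture generation.

#' Write / read conformational ensembles as TSV
#'
#' Long-format tab-separated text: one conformation per row with
#' columns `context`, `id`, `chi1`..`chi4` (blank for unused chi),
#' `potential_energy` (optional, blank allowed) and `free_energy`.
#'
#' @param ensembles Named list of [conformation_ensemble()] objects
#'   keyed by context.
#' @param path File path.
#' @return `write_ensemble_tsv`: invisibly, the path;
#'   `read_ensemble_tsv`: a named list of ensembles.
#' @export
write_ensemble_tsv <- function(ensembles, path) {
  rows <- lapply(names(ensembles), function(key) {
    e <- ensembles[[key]]
    chi <- matrix(NA_real_, nrow(e$torsions), 4L)
    chi[, seq_len(ncol(e$torsions))] <- e$torsions
    data.frame(context = key, id = e$ids,
               chi1 = chi[, 1L], chi2 = chi[, 2L],
               chi3 = chi[, 3L], chi4 = chi[, 4L],
               potential_energy = if (is.null(e$potential_energy))
                 NA_real_ else e$potential_energy,
               free_energy = e$free_energy, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_ensemble_tsv
#' @export
read_ensemble_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("context", "id", paste0("chi", 1:4), "free_energy")
  if (!all(need %in% names(tab)))
    stop("ensemble TSV must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(tab, tab$context), function(g) {
    chi <- as.matrix(g[, paste0("chi", 1:4)])
    chi <- chi[, colSums(!is.na(chi)) > 0, drop = FALSE]
    pe <- if ("potential_energy" %in% names(g) &&
              !all(is.na(g$potential_energy))) g$potential_energy else NULL
    conformation_ensemble(chi, g$free_energy, potential_energy = pe,
                          ids = g$id)
  })
  out
}

#' Read a side-chain test set from TSV
#'
#' Columns `prev`, `central`, `nxt`, `chi1`..`chi4` (blank for unused).
#'
#' @param path File path.
#' @return Data frame suitable for [coverage_report()].
#' @export
read_testset_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("prev", "central", "nxt", "chi1")
  if (!all(need %in% names(tab)))
    stop("test-set TSV must have columns prev, central, nxt, chi1..chi4")
  for (col in paste0("chi", 1:4))
    if (!col %in% names(tab)) tab[[col]] <- NA_real_
  tab
}

#' Generate the package's synthetic fixtures
#'
#' Writes, into `dir`, a planted-rotamer ensemble TSV, a 3-model
#' synthetic serine fragment PDB with its sidecar energy table, and a
#' toy-chain potential definition; the seed is embedded in each file
#' name so fixture sets from different seeds can coexist.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, a named character vector of the written paths.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  tag <- sprintf("seed%d", seed)

  centers <- rbind(c(-60, 180, 60), c(60, -60, 180), c(180, 60, -60))
  fe <- c(0, 0.5, 1.2)
  ens <- list(
    "GLY-GLN-GLY" = sample_planted_ensemble(centers, fe, n_draws = 120),
    "ALA-SER-ALA" = sample_planted_ensemble(matrix(c(-65, 62, 178), 3L, 1L),
                                            c(0.1, 0, 0.8), n_draws = 120))
  paths <- c(ensembles = file.path(dir, paste0("ensembles_", tag, ".tsv")))
  write_ensemble_tsv(ens, paths[["ensembles"]])

  models <- lapply(c(-60, 60, 180), function(chi)
    build_sidechain_fragment("SER", chi))
  paths[["pdb"]] <- file.path(dir, paste0("serine_models_", tag, ".pdb"))
  write_multimodel_pdb(models, paths[["pdb"]])
  paths[["energies"]] <- file.path(dir, paste0("serine_models_", tag,
                                               "_energies.tsv"))
  write_energy_table(data.frame(model_id = 1:3,
                                potential_energy = c(-1.2, -0.8, -1.5),
                                free_energy = c(-0.9, -0.5, -1.1)),
                     paths[["energies"]])

  paths[["toy"]] <- file.path(dir, paste0("toy_chain_", tag, ".txt"))
  writeLines(c("# rotbh toy rotamer-chain definition",
               sprintf("n_residues\t%d", 4L),
               sprintf("wells_per_residue\t%d", 3L),
               sprintf("seed\t%d", seed)),
             paths[["toy"]])
  invisible(paths)
}

#' Read a toy-chain definition file
#'
#' @param path Path written by [make_fixtures()].
#' @return A `"rotamer_chain"` built from the recorded parameters.
#' @export
read_toy_definition <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  kv <- do.call(rbind, strsplit(lines, "\t"))
  val <- function(key) as.integer(kv[kv[, 1L] == key, 2L])
  make_rotamer_chain(n_residues = val("n_residues"),
                     wells_per_residue = val("wells_per_residue"),
                     seed = val("seed"))
}
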