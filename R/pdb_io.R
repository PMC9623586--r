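# Multi-model PDB ensembles and their sidecar energy tables.
#
# Coordinates travel as multi-model PDB (parsed with bio3d); per-model
# potential and free energies travel in a tab-separated sidecar
# (model_id, potential_energy, free_energy), which is robust across PDB
# dialects that disagree about REMARK records.

#' Read a multi-model PDB file as an ensemble bundle
#'
#' Models are returned in file order with residue and atom naming
#' preserved; ACE/NME capping groups are recognized in the sequence.
#' Models missing side-chain atoms required by the chi definitions of
#' their residues are flagged (and can then be excluded from library
#' construction), not silently dropped.
#'
#' @param path Path to a PDB file with MODEL/ENDMDL records (a single
#'   uncapped model is treated as one model).
#' @return An object of class `"ensemble_bundle"`: list with `models`
#'   (list of [conformation()] objects), `atoms`, `sequence` (data
#'   frame `resno`, `resid`), `capped` (logical: ACE and NME present),
#'   `flagged` (integer indices of models with missing side-chain
#'   atoms), `source`.
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  coord <- grepl("^(ATOM|HETATM)", lines)
  if (!any(coord)) stop("no coordinate records in ", path)
  bad <- which(coord & nchar(lines) < 54)
  if (length(bad) > 0L)
    stop("malformed coordinate record at line ", bad[1L], " of ", path)
  model_starts <- grep("^MODEL", lines)
  blocks <- if (length(model_starts) == 0L) list(lines) else {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(model_starts))
      stop("unbalanced MODEL/ENDMDL records (line ",
           model_starts[length(model_starts)], ")")
    lapply(seq_along(model_starts), function(i)
      lines[(model_starts[i] + 1L):(ends[i] - 1L)])
  }
  read_block <- function(block, i) {
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp))
    writeLines(c(block, "END"), tmp)
    pdb <- tryCatch(bio3d::read.pdb(tmp, rm.alt = TRUE, verbose = FALSE),
                    error = function(e) stop("malformed PDB model ", i,
                                             " in ", path, ": ",
                                             conditionMessage(e)))
    conformation(matrix(pdb$xyz, ncol = 3L, byrow = TRUE),
                 data.frame(resno = pdb$atom$resno,
                            resid = toupper(pdb$atom$resid),
                            elety = pdb$atom$elety, stringsAsFactors = FALSE))
  }
  models <- lapply(seq_along(blocks), function(i) read_block(blocks[[i]], i))
  ref <- models[[which.max(vapply(models, function(m) nrow(m$atoms),
                                  integer(1L)))]]
  seq_tab <- unique(ref$atoms[, c("resno", "resid")])
  seq_tab <- seq_tab[order(seq_tab$resno), ]
  rownames(seq_tab) <- NULL
  defs <- chi_definitions()
  model_complete <- function(m) {
    for (i in seq_len(nrow(seq_tab))) {
      need <- defs[defs$resid == seq_tab$resid[i], ]
      if (nrow(need) == 0L) next
      have <- m$atoms$elety[m$atoms$resno == seq_tab$resno[i]]
      if (length(setdiff(unique(c(need$a1, need$a2, need$a3, need$a4)),
                         have)) > 0L)
        return(FALSE)
    }
    !anyNA(m$xyz)
  }
  flagged <- which(!vapply(models, model_complete, logical(1L)))
  structure(list(models = models, atoms = ref$atoms, sequence = seq_tab,
                 capped = all(c("ACE", "NME") %in% seq_tab$resid),
                 flagged = flagged, source = path),
            class = "ensemble_bundle")
}

#' Write an ensemble of conformations as a multi-model PDB file
#'
#' @param models List of [conformation()] objects sharing one topology,
#'   or a single conformation.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_multimodel_pdb <- function(models, path) {
  if (inherits(models, "conformation")) models <- list(models)
  at <- models[[1L]]$atoms
  xyz <- do.call(rbind, lapply(models, function(m) .xyz_vector(m$xyz)))
  pdb <- list(atom = data.frame(type = "ATOM", eleno = seq_len(nrow(at)),
                                elety = at$elety, alt = NA, resid = at$resid,
                                chain = "A", resno = at$resno, insert = NA,
                                x = models[[1L]]$xyz[, 1L],
                                y = models[[1L]]$xyz[, 2L],
                                z = models[[1L]]$xyz[, 3L],
                                o = 1, b = 0, segid = NA, elesy = NA,
                                charge = NA, stringsAsFactors = FALSE),
              xyz = xyz)
  class(pdb) <- "pdb"
  bio3d::write.pdb(pdb, file = path, xyz = xyz)
  invisible(path)
}

#' @export
print.ensemble_bundle <- function(x, ...) {
  cat("Ensemble bundle:", length(x$models), "models,",
      nrow(x$sequence), "residues",
      if (x$capped) "(ACE/NME capped)" else "", "\n")
  if (length(x$flagged))
    cat("  flagged models (missing side-chain atoms):",
        paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a sidecar energy table
#'
#' Tab-separated columns `model_id`, `potential_energy`, `free_energy`.
#'
#' @param energies Data frame with those columns.
#' @param path File path.
#' @return `write_energy_table`: invisibly, the path;
#'   `read_energy_table`: the data frame.
#' @export
write_energy_table <- function(energies, path) {
  stopifnot(all(c("model_id", "potential_energy", "free_energy")
                %in% names(energies)))
  utils::write.table(energies, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_energy_table
#' @export
read_energy_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("model_id", "potential_energy", "free_energy")
  if (!all(need %in% names(tab)))
    stop("sidecar energy table must have columns: ",
         paste(need, collapse = ", "))
  tab
}

#' Extract a context-keyed ensemble from a bundle and its energies
#'
#' Computes the central residue's chi torsions for every unflagged model
#' and pairs them with the sidecar free energies.
#'
#' @param bundle An `"ensemble_bundle"`.
#' @param energies Sidecar data frame (see [read_energy_table()]); row
#'   order matches model order.
#' @param residue Residue number of the central residue.
#' @return A [conformation_ensemble()].
#' @export
ensemble_from_bundle <- function(bundle, energies, residue) {
  stopifnot(inherits(bundle, "ensemble_bundle"))
  keep <- setdiff(seq_along(bundle$models), bundle$flagged)
  if (length(keep) == 0L) stop("no usable models in bundle")
  n_chi <- sidechain_chi_count(
    bundle$sequence$resid[bundle$sequence$resno == residue])
  torsions <- matrix(vapply(bundle$models[keep],
                            function(m) extract_sidechain_torsions(m, residue),
                            numeric(n_chi)),
                     ncol = n_chi, byrow = TRUE)
  conformation_ensemble(torsions, energies$free_energy[keep],
                        potential_energy = energies$potential_energy[keep],
                        ids = energies$model_id[keep])
}

#' Sequence context of a residue within a bundle
#'
#' @param bundle An `"ensemble_bundle"`.
#' @param residue Central residue number.
#' @return Context key "PREV-CENT-NEXT".
#' @export
bundle_context <- function(bundle, residue) {
  s <- bundle$sequence
  i <- match(residue, s$resno)
  if (is.na(i)) stop("residue ", residue, " not in bundle")
  prev <- if (i > 1L) s$resid[i - 1L] else "NA"
  nxt <- if (i < nrow(s)) s$resid[i + 1L] else "NA"
  context_key(prev, s$resid[i], nxt)
}
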