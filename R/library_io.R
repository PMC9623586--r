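# Tab-separated text serialization of rotamer libraries.
#
# One rotamer per line: prev, central, next, chi1..chi4 means, chi1..chi4
# standard deviations (blank for unused chi), probability, member count.
# A '#'-prefixed header carries the format version and the build
# parameters, so any library file is self-describing and diffable.

.library_format_version <- 1L
.num_fmt <- "%.6f"

#' Write a rotamer library to a tab-separated text file
#'
#' @param library A `"rotamer_library"`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @seealso [read_library()]
#' @export
write_library <- function(library, path) {
  stopifnot(inherits(library, "rotamer_library"))
  md <- library$metadata
  e <- library$entries
  key <- context_key(e$prev, e$central, e$nxt)
  e <- e[order(key, -e$probability), , drop = FALSE]
  fmt <- function(x) ifelse(is.na(x), "", sprintf(.num_fmt, x))
  lines <- c(
    sprintf("# rotbh rotamer library format %d", .library_format_version),
    sprintf("# temperature_K=%s", format(md$temperature)),
    sprintf("# cutoff_deg=%s", format(md$cutoff)),
    sprintf("# prune=%s", format(md$prune)),
    paste(.library_columns(), collapse = "\t"))
  if (nrow(e) > 0L) {
    body <- apply(cbind(e$prev, e$central, e$nxt, e$n_chi,
                        fmt(e$chi1_mean), fmt(e$chi2_mean),
                        fmt(e$chi3_mean), fmt(e$chi4_mean),
                        fmt(e$chi1_sd), fmt(e$chi2_sd),
                        fmt(e$chi3_sd), fmt(e$chi4_sd),
                        sprintf(.num_fmt, e$probability),
                        e$member_count),
                  1L, paste, collapse = "\t")
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a rotamer library from its text representation
#'
#' Validates the format version, the presence of the build parameters in
#' the header, and per-row sanity (probabilities in `[0, 1]`,
#' non-negative spreads, positive member counts).  A write/read/write
#' round trip is byte-identical.
#'
#' @param path Path to a library file written by [write_library()].
#' @return A `"rotamer_library"`.
#' @export
read_library <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  if (length(hdr) == 0L ||
      !grepl("^# rotbh rotamer library format ", hdr[1L]))
    stop("not a rotbh rotamer library file: ", path)
  ver <- as.integer(sub("^# rotbh rotamer library format ", "", hdr[1L]))
  if (is.na(ver) || ver != .library_format_version)
    stop("unsupported library format version: ", ver)
  get_field <- function(name) {
    ln <- grep(paste0("^# ", name, "="), hdr, value = TRUE)
    if (length(ln) != 1L) stop("library header missing field: ", name)
    as.numeric(sub(paste0("^# ", name, "="), "", ln))
  }
  md <- list(temperature = get_field("temperature_K"),
             cutoff = get_field("cutoff_deg"),
             prune = get_field("prune"),
             format_version = ver)
  body <- lines[!grepl("^#", lines)]
  if (length(body) == 0L || !identical(strsplit(body[1L], "\t")[[1L]],
                                       .library_columns()))
    stop("library column header missing or malformed")
  body <- body[-1L]
  parse_row <- function(ln, i) {
    f <- strsplit(ln, "\t")[[1L]]
    if (length(f) != 14L)
      stop("malformed library row ", i, ": expected 14 fields, got ", length(f))
    num <- function(s) if (s == "") NA_real_ else as.numeric(s)
    r <- data.frame(prev = f[1L], central = f[2L], nxt = f[3L],
                    n_chi = as.integer(f[4L]),
                    chi1_mean = num(f[5L]), chi2_mean = num(f[6L]),
                    chi3_mean = num(f[7L]), chi4_mean = num(f[8L]),
                    chi1_sd = num(f[9L]), chi2_sd = num(f[10L]),
                    chi3_sd = num(f[11L]), chi4_sd = num(f[12L]),
                    probability = as.numeric(f[13L]),
                    member_count = as.integer(f[14L]),
                    stringsAsFactors = FALSE)
    if (is.na(r$probability) || r$probability < 0 || r$probability > 1)
      stop("library row ", i, ": probability out of [0, 1]")
    if (is.na(r$n_chi) || r$n_chi < 1L || r$n_chi > 4L)
      stop("library row ", i, ": chi count out of range")
    sds <- as.numeric(r[paste0("chi", seq_len(r$n_chi), "_sd")])
    if (any(is.na(sds)) || any(sds < 0))
      stop("library row ", i, ": missing or negative chi standard deviation")
    if (is.na(r$member_count) || r$member_count < 1L)
      stop("library row ", i, ": member count must be >= 1")
    r
  }
  entries <- if (length(body) == 0L)
    utils::read.table(text = "", col.names = .library_columns())
  else do.call(rbind, lapply(seq_along(body),
                             function(i) parse_row(body[i], i)))
  rownames(entries) <- NULL
  structure(list(entries = entries, metadata = md),
            class = "rotamer_library")
}
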