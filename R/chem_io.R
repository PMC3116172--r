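# Structure and activity-table input/output. Parsing of SDF records is
# delegated to ChemmineR (and ChemmineOB for SMILES interpretation); this
# layer converts to the package's light heavy-atom-graph records and keeps
# per-record failure reporting explicit.

sdf_to_mol <- function(sdf, id) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  atoms <- data.frame(element = elements, charge = 0L, aromatic = FALSE,
                      stringsAsFactors = FALSE)
  if (is.null(bb) || nrow(bb) == 0L) {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  } else {
    bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  }
  mol_perceive_aromatic(molecule(id, atoms, bonds))
}

# Minimal V2000 writer for the package's own records; files it produces are
# read back through ChemmineR (round-trip tested).
mol_to_sdf_block <- function(mol) {
  n <- mol_natoms(mol); nb <- nrow(mol$bonds)
  lines <- c(mol$id, "  bqsar", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  for (i in seq_len(n))
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              0, 0, 0, mol$atoms$element[i]))
  for (i in seq_len(nb))
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              mol$bonds$a1[i], mol$bonds$a2[i], mol$bonds$order[i]))
  chg <- which(mol$atoms$charge != 0L)
  if (length(chg))
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg)),
                             paste0(sprintf("%4d%4d", chg, mol$atoms$charge[chg]),
                                    collapse = "")))
  c(lines, "M  END", "$$$$")
}

#' Write molecules to an SDF (V2000) file
#'
#' @param mols List of `bq_mol` objects (or a `bq_library`).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_structures <- function(mols, path) {
  if (inherits(mols, "bq_library")) mols <- lapply(mols$records, `[[`, "molecule")
  txt <- unlist(lapply(mols, mol_to_sdf_block))
  writeLines(txt, path)
  invisible(path)
}

# Parse one V2000 record (character vector of lines). Bond-free records
# (single atoms, rare but legal) are handled directly because the delegated
# parser mishandles a zero-row bond block.
parse_sdf_record <- function(rec, id) {
  counts <- rec[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (!is.na(na) && !is.na(nb) && nb == 0L && na >= 1L &&
      length(rec) >= 4L + na) {
    el <- vapply(strsplit(trimws(rec[5:(4 + na)]), "\\s+"), `[[`, "", 4)
    return(molecule(id, data.frame(element = el)))
  }
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(rec, tf)
  sset <- suppressWarnings(ChemmineR::read.SDFset(tf, skipErrors = TRUE))
  if (length(sset) != 1L || !ChemmineR::validSDF(sset))
    stop("invalid SDF record")
  sdf_to_mol(sset[[1]], id)
}

#' Read compound structures from an SDF or SMILES file
#'
#' SDF records are parsed one by one so that a malformed record is reported
#' (in the `failures` attribute) without discarding the rest of the file.
#' SMILES files contain one molecule per line, optionally followed by a
#' whitespace-separated identifier; interpretation requires ChemmineOB.
#'
#' @param path File path.
#' @param format Either `"sdf"` or `"smiles"`.
#' @return A list of `bq_mol` objects, in file order, with attribute
#'   `failures`: a character vector describing records that failed to parse.
#' @export
read_structures <- function(path, format = c("sdf", "smiles")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read structure file: ", path, call. = FALSE)
  mols <- list(); failures <- character()
  if (format == "sdf") {
    txt <- readLines(path, warn = FALSE)
    ends <- which(trimws(txt) == "$$$$")
    if (!length(ends)) ends <- length(txt)
    starts <- c(1L, head(ends, -1L) + 1L)
    for (k in seq_along(starts)) {
      rec <- txt[starts[k]:ends[k]]
      if (all(!nzchar(trimws(rec)))) next
      id <- trimws(rec[1]); if (!nzchar(id)) id <- sprintf("mol_%d", k)
      m <- tryCatch(parse_sdf_record(rec, id), error = function(e) e)
      if (inherits(m, "error")) {
        failures <- c(failures, sprintf("record %d (%s): %s", k, id, conditionMessage(m)))
      } else mols[[length(mols) + 1L]] <- m
    }
  } else {
    if (!requireNamespace("ChemmineOB", quietly = TRUE))
      stop("reading SMILES requires the ChemmineOB package", call. = FALSE)
    ln <- readLines(path, warn = FALSE)
    ln <- ln[nzchar(trimws(ln))]
    for (k in seq_along(ln)) {
      parts <- strsplit(trimws(ln[k]), "\\s+")[[1]]
      smi <- parts[1]
      id <- if (length(parts) > 1L) parts[2] else sprintf("mol_%d", k)
      m <- tryCatch({
        txt <- ChemmineOB::convertFormat("SMI", "SDF", paste0(smi, "\n"))
        rec <- strsplit(txt, "\n", fixed = TRUE)[[1]]
        if (length(rec) < 5L) stop("SMILES did not parse")
        parse_sdf_record(rec, id)
      }, error = function(e) e)
      if (inherits(m, "error")) {
        failures <- c(failures, sprintf("line %d (%s): %s", k, smi, conditionMessage(m)))
      } else mols[[length(mols) + 1L]] <- m
    }
  }
  if (!length(mols))
    stop("no valid molecules in ", path,
         if (length(failures)) paste0(" (", length(failures), " parse failures)"),
         call. = FALSE)
  ids <- vapply(mols, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate molecule ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  attr(mols, "failures") <- failures
  mols
}

#' Read a per-compound activity table
#'
#' Expects a comma-separated, UTF-8, header-first CSV whose first column is
#' the compound id and whose remaining columns are IC50 values (ug/mL) for
#' one cell line each. Blank cells become missing values; any non-numeric,
#' non-blank cell is an error naming the offending row and column.
#'
#' @param path CSV file path.
#' @return A numeric matrix (compounds x cell lines) with compound ids as row
#'   names.
#' @export
read_activity_table <- function(path) {
  if (!file.exists(path)) stop("cannot read activity table: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  if (ncol(raw) < 2L) stop("activity table needs an id column plus at least one cell line",
                           call. = FALSE)
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    stop("duplicate compound id in activity table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  cells <- names(raw)[-1]
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(cells),
                 dimnames = list(ids, cells))
  for (j in seq_along(cells)) {
    col <- raw[[j + 1L]]
    blank <- !nzchar(col)
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!blank & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric IC50 at row %d, column '%s': '%s'",
                   bad[1], cells[j], col[bad[1]]), call. = FALSE)
    if (any(num[!is.na(num)] <= 0))
      stop(sprintf("IC50 must be positive (column '%s')", cells[j]), call. = FALSE)
    vals[, j] <- num
  }
  vals
}

#' Join molecules with their activity table into a compound library
#'
#' Records keep the molecule input order, which drives the deterministic
#' diversity ranking downstream.
#'
#' @param molecules List of `bq_mol` objects.
#' @param activities Numeric matrix from [read_activity_table()] (rownames =
#'   compound ids), or anything coercible to one.
#' @param permissive If `TRUE`, molecules without an activity row are kept
#'   with all-missing activities (and listed in the library's `warnings`);
#'   if `FALSE` (default) they are an error.
#' @return A `bq_library`: records (molecule + per-cell-line activities),
#'   the ordered cell-line names, and any join warnings.
#' @export
join_library <- function(molecules, activities, permissive = FALSE) {
  activities <- as.matrix(activities)
  ids <- vapply(molecules, `[[`, "", "id")
  if (!length(intersect(ids, rownames(activities))))
    stop("no molecule id matches any activity row", call. = FALSE)
  missing <- setdiff(ids, rownames(activities))
  if (length(missing) && !permissive)
    stop("molecules without activity rows: ", paste(missing, collapse = ", "),
         " (set permissive = TRUE to keep them)", call. = FALSE)
  warnings <- character()
  if (length(missing))
    warnings <- sprintf("no activity row for '%s'; activities set missing", missing)
  unmatched_rows <- setdiff(rownames(activities), ids)
  if (length(unmatched_rows))
    warnings <- c(warnings, sprintf("activity row '%s' has no molecule", unmatched_rows))
  cell_lines <- colnames(activities)
  records <- lapply(seq_along(molecules), function(i) {
    act <- if (ids[i] %in% rownames(activities)) activities[ids[i], ] else
      stats::setNames(rep(NA_real_, length(cell_lines)), cell_lines)
    list(molecule = molecules[[i]], activities = act)
  })
  structure(list(records = records, cell_lines = cell_lines, warnings = warnings),
            class = "bq_library")
}

#' @export
print.bq_library <- function(x, ...) {
  cat(sprintf("<bq_library: %d compounds, cell lines: %s>\n",
              length(x$records), paste(x$cell_lines, collapse = ", ")))
  if (length(x$warnings)) cat(" warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' @export
length.bq_library <- function(x) length(x$records)

#' Compound ids of a library, in record order
#' @param library A `bq_library`.
#' @return Character vector.
#' @export
library_ids <- function(library) {
  vapply(library$records, function(r) r$molecule$id, "")
}

#' Activity matrix of a library
#' @param library A `bq_library`.
#' @return Numeric matrix (compounds x cell lines), NA for missing.
#' @export
activity_matrix <- function(library) {
  m <- do.call(rbind, lapply(library$records, `[[`, "activities"))
  dimnames(m) <- list(library_ids(library), library$cell_lines)
  m
}

#' Subset a library by record index
#' @param x A `bq_library`.
#' @param i Integer or logical index over records.
#' @param ... Unused.
#' @export
`[.bq_library` <- function(x, i, ...) {
  structure(list(records = x$records[i], cell_lines = x$cell_lines,
                 warnings = x$warnings), class = "bq_library")
}

#' Write a one-row-per-compound summary CSV
#'
#' Columns: id, heavy-atom count, molecular formula and weight, then one IC50
#' column per cell line.
#'
#' @param library A `bq_library`.
#' @param path Output CSV path.
#' @return Invisibly, the summary data frame.
#' @export
write_library_summary <- function(library, path) {
  mols <- lapply(library$records, `[[`, "molecule")
  df <- data.frame(
    id = library_ids(library),
    n_atoms = vapply(mols, mol_natoms, 0L),
    formula = vapply(mols, mol_formula, ""),
    mw = round(vapply(mols, mol_weight, 0), 2),
    check.names = FALSE
  )
  df <- cbind(df, as.data.frame(activity_matrix(library)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
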