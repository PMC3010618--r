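#' Gap dialect for plain-text files
#'
#' Downstream tools often serialize undefined ("gap") entries as large
#' off-scale sentinel values; self-describing files use NaN/NA tokens. A
#' `GapDialect` states how gaps are recognized on read. On write this package
#' always emits `NaN` (the self-describing choice). On read, NaN tokens
#' (`NaN`, `nan`, `NA`) are always gaps; in `THRESHOLD` mode any value with
#' absolute value >= `threshold` is additionally a gap.
#'
#' @param mode `"NAN_SENTINEL"` (default) or `"THRESHOLD"`.
#' @param threshold Positive real; used only in `THRESHOLD` mode.
#' @return A `GapDialect`.
#' @export
gap_dialect <- function(mode = c("NAN_SENTINEL", "THRESHOLD"),
                        threshold = Inf) {
  mode <- match.arg(mode)
  if (mode == "THRESHOLD" && (!is.finite(threshold) || threshold <= 0))
    stop("gap_dialect: THRESHOLD mode needs a finite positive threshold")
  structure(list(mode = mode, threshold = as.numeric(threshold)[1]),
            class = "GapDialect")
}

is_gap_value <- function(x, dialect) {
  g <- is.na(x)
  if (dialect$mode == "THRESHOLD") g <- g | abs(x) >= dialect$threshold
  g
}

read_lines_clean <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^[[:space:]]*#", lines)
  list(lines = lines, keep = keep)
}

parse_numeric_fields <- function(line, lineno, path) {
  fields <- strsplit(trimws(line), "[,[:space:]]+")[[1]]
  fields <- fields[nzchar(fields)]
  vals <- suppressWarnings(as.numeric(fields))
  bad <- is.na(vals) & !(toupper(fields) %in% c("NA", "NAN"))
  if (any(bad))
    stop("parse error at line ", lineno, " of ", path, ": '",
         fields[which(bad)[1]], "' is not numeric")
  vals
}

#' Read / write a 1D flexibility signal
#'
#' Signal files are delimited text with one value per line, or two columns
#' (index, value); lines starting with `#` are comments. Gap positions are
#' written as `NaN` and recognized on read per the [gap_dialect()].
#'
#' @param path File path.
#' @param dialect A `GapDialect`.
#' @param protein_id Id for the resulting signal (default: file base name).
#' @param kind Signal kind; see [flexibility_signal()].
#' @return `read_signal`: a `FlexibilitySignal`. `write_signal`: the path,
#'   invisibly.
#' @export
read_signal <- function(path, dialect = gap_dialect(),
                        protein_id = NULL, kind = "OTHER") {
  lc <- read_lines_clean(path)
  vals <- numeric(0)
  for (i in seq_along(lc$lines)) {
    if (!lc$keep[i] || !nzchar(trimws(lc$lines[i]))) next
    f <- parse_numeric_fields(lc$lines[i], i, path)
    if (length(f) == 1) vals <- c(vals, f)
    else if (length(f) == 2) vals <- c(vals, f[2])
    else stop("parse error at line ", i, " of ", path,
              ": expected 1 or 2 columns, got ", length(f))
  }
  if (length(vals) == 0) stop("read_signal: empty signal file ", path)
  gaps <- is_gap_value(vals, dialect)
  vals[gaps] <- 0
  if (is.null(protein_id))
    protein_id <- tools::file_path_sans_ext(basename(path))
  flexibility_signal(protein_id, vals, kind = kind, gap_mask = gaps)
}

#' @rdname read_signal
#' @param sig A `FlexibilitySignal` to write.
#' @export
write_signal <- function(sig, path) {
  validate_signal(sig)
  vals <- sig$values
  vals[sig$gap_mask] <- NaN
  writeLines(c(sprintf("# flexcompare signal: %s (%s)", sig$protein_id,
                       sig$kind),
               sprintf("%.17g", vals)), path)
  invisible(path)
}

#' Read / write a susceptibility matrix
#'
#' Matrix files are dense whitespace- or comma-delimited m x m numeric text;
#' `#` lines are comments; gaps are `NaN` (or off-scale values in `THRESHOLD`
#' dialects). Symmetry of the non-gap values is validated to 1e-9.
#'
#' @inheritParams read_signal
#' @return `read_matrix`: a `SusceptibilityImage`. `write_matrix`: the path,
#'   invisibly.
#' @export
read_matrix <- function(path, dialect = gap_dialect(), protein_id = NULL) {
  lc <- read_lines_clean(path)
  rows <- list()
  for (i in seq_along(lc$lines)) {
    if (!lc$keep[i] || !nzchar(trimws(lc$lines[i]))) next
    rows[[length(rows) + 1]] <- parse_numeric_fields(lc$lines[i], i, path)
  }
  if (length(rows) == 0) stop("read_matrix: empty matrix file ", path)
  widths <- lengths(rows)
  if (length(unique(widths)) != 1)
    stop("read_matrix: ragged rows in ", path, " (widths ",
         paste(unique(widths), collapse = ", "), ")")
  M <- do.call(rbind, rows)
  if (nrow(M) != ncol(M))
    stop("read_matrix: expected a square matrix, got ", nrow(M), " x ",
         ncol(M), " in ", path)
  gaps <- matrix(is_gap_value(as.numeric(M), dialect), nrow(M))
  gaps <- gaps | t(gaps)   # a gap is undefined for both (j,k) and (k,j)
  M[gaps] <- 0
  if (is.null(protein_id))
    protein_id <- tools::file_path_sans_ext(basename(path))
  susceptibility_image(protein_id, M, gap_mask = gaps)
}

#' @rdname read_matrix
#' @param img A `SusceptibilityImage` to write.
#' @export
write_matrix <- function(img, path) {
  validate_image(img)
  M <- img$chi
  M[img$gap_mask] <- NaN
  lines <- apply(M, 1, function(r) paste(sprintf("%.17g", r),
                                         collapse = "\t"))
  writeLines(c(sprintf("# flexcompare susceptibility matrix: %s (m=%d)",
                       img$protein_id, img$m), lines), path)
  invisible(path)
}

#' Read / write a rigidity-state ensemble
#'
#' An ensemble is either a directory of per-realization matrix files (read in
#' lexicographic order) or a single file with realizations separated by blank
#' lines. Entries must be integers in \{-1, 0, 1\}.
#'
#' @param dir_or_path Directory or file path.
#' @param protein_id Id for the ensemble (default: base name).
#' @return `read_ensemble`: a validated `RigidityStateEnsemble`.
#'   `write_ensemble`: the path, invisibly.
#' @export
read_ensemble <- function(dir_or_path, protein_id = NULL) {
  if (is.null(protein_id))
    protein_id <- tools::file_path_sans_ext(basename(dir_or_path))
  if (dir.exists(dir_or_path)) {
    files <- sort(list.files(dir_or_path, full.names = TRUE))
    files <- files[!dir.exists(files)]
    if (length(files) == 0)
      stop("read_ensemble: no realizations in directory ", dir_or_path)
    blocks <- lapply(files, function(f) readLines(f, warn = FALSE))
  } else {
    lines <- readLines(dir_or_path, warn = FALSE)
    lines <- lines[!grepl("^[[:space:]]*#", lines)]
    blank <- !nzchar(trimws(lines))
    grp <- cumsum(c(TRUE, diff(blank) == -1))  # new group after blank run
    grp[blank] <- NA
    blocks <- split(lines[!blank], grp[!blank])
    if (length(blocks) == 0)
      stop("read_ensemble: no realizations in ", dir_or_path)
  }
  reals <- lapply(blocks, function(b) {
    rows <- lapply(seq_along(b), function(i) {
      if (!nzchar(trimws(b[i])) || grepl("^[[:space:]]*#", b[i]))
        return(NULL)
      parse_numeric_fields(b[i], i, dir_or_path)
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    M <- do.call(rbind, rows)
    if (any(M != round(M), na.rm = TRUE))
      stop("read_ensemble: non-integer rigidity state in ", dir_or_path)
    storage.mode(M) <- "integer"
    M
  })
  rigidity_ensemble(protein_id, unname(reals))
}

#' @rdname read_ensemble
#' @param ens A `RigidityStateEnsemble` to write (single-file layout).
#' @param path Output file path.
#' @export
write_ensemble <- function(ens, path) {
  validate_ensemble(ens)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# flexcompare rigidity ensemble: %s (m=%d, R=%d)",
                     ens$protein_id, ens$m, length(ens$realizations)), con)
  for (r in seq_along(ens$realizations)) {
    M <- ens$realizations[[r]]
    writeLines(apply(M, 1, paste, collapse = "\t"), con)
    if (r < length(ens$realizations)) writeLines("", con)
  }
  invisible(path)
}

#' Read amino-acid sequences from a FASTA file
#'
#' Records are parsed with Biostrings and validated against the 20 standard
#' one-letter amino-acid codes; `'X'` is permitted (and becomes a gap when
#' the sequence is turned into a hydrophobicity signal). Sequences are
#' uppercased.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences (names = record ids).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("read_fasta: no records in ", path)
  seqs <- toupper(gsub("[[:space:]]", "", as.character(set)))
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, "", 1)
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[i], "")[[1]]
    bad <- !(chars %in% c(AA_CODES, "X"))
    if (any(bad))
      stop("read_fasta: record '", ids[i], "' has non-amino-acid ",
           "character '", chars[which(bad)[1]], "' at position ",
           which(bad)[1])
  }
  stats::setNames(seqs, ids)
}

#' Read / write registration control points
#'
#' Control-point files have 4 numeric columns per row: `x_moving`,
#' `y_moving`, `x_base`, `y_base`, with 1-based pixel coordinates, x =
#' column, y = row, origin at top-left. At least 2 point pairs are required
#' (the minimum determining a similarity transform).
#'
#' @param path File path.
#' @return `read_control_points`: an n x 4 numeric matrix with columns
#'   `x_moving`, `y_moving`, `x_base`, `y_base`.
#' @export
read_control_points <- function(path) {
  lc <- read_lines_clean(path)
  rows <- list()
  for (i in seq_along(lc$lines)) {
    if (!lc$keep[i] || !nzchar(trimws(lc$lines[i]))) next
    f <- parse_numeric_fields(lc$lines[i], i, path)
    if (length(f) != 4)
      stop("read_control_points: line ", i, " of ", path,
           " has ", length(f), " columns, expected 4")
    rows[[length(rows) + 1]] <- f
  }
  if (length(rows) < 2)
    stop("read_control_points: at least 2 control points required, got ",
         length(rows))
  pts <- do.call(rbind, rows)
  colnames(pts) <- c("x_moving", "y_moving", "x_base", "y_base")
  pts
}

#' @rdname read_control_points
#' @param points n x 4 numeric matrix of control points to write.
#' @export
write_control_points <- function(points, path) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 4, nrow(points) >= 2)
  writeLines(c("# x_moving y_moving x_base y_base (1-based; x=column, y=row, origin top-left)",
               apply(points, 1, function(r) paste(sprintf("%.17g", r),
                                                  collapse = "\t"))),
             path)
  invisible(path)
}

#' Write / read a pair-distance table
#'
#' The wide format mirrors printed family tables: one column per protein pair
#' (labelled `"A-B"`), and two value rows, `Euclidean distance` and
#' `Gap measure`. An optional long-format companion file (`pair`,
#' `euclidean`, `gap_measure`) is convenient for scatter plots.
#'
#' @param records List of SYMMETRIZED `PairDistance` records with distinct
#'   pairs.
#' @param path Output path for the wide table.
#' @param long_path Optional output path for the long format.
#' @return `write_distance_table`: the path, invisibly.
#'   `read_distance_table`: a data.frame with columns `pair`, `euclidean`,
#'   `gap_measure`.
#' @export
write_distance_table <- function(records, path, long_path = NULL) {
  stopifnot(all(vapply(records, inherits, TRUE, "PairDistance")))
  dirs <- vapply(records, function(r) r$direction, "")
  if (any(dirs != "SYMMETRIZED"))
    stop("write_distance_table: all records must be SYMMETRIZED, got ",
         paste(unique(dirs), collapse = ", "))
  labels <- vapply(records, function(r) paste0(r$id_a, "-", r$id_b), "")
  if (anyDuplicated(labels))
    stop("write_distance_table: duplicate pair ",
         labels[anyDuplicated(labels)])
  eu <- vapply(records, function(r) r$euclidean, 0)
  gm <- vapply(records, function(r) r$gap_measure, 0)
  lines <- c(paste(c("measure", labels), collapse = "\t"),
             paste(c("Euclidean distance",
                     sprintf("%.17g", eu)), collapse = "\t"),
             paste(c("Gap measure",
                     sprintf("%.17g", gm)), collapse = "\t"))
  writeLines(lines, path)
  if (!is.null(long_path)) {
    writeLines(c("pair\teuclidean\tgap_measure",
                 sprintf("%s\t%.17g\t%.17g", labels, eu, gm)), long_path)
  }
  invisible(path)
}

#' @rdname write_distance_table
#' @export
read_distance_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  pairs <- header[-1]
  if (length(cells) < 3 && length(pairs) > 0)
    stop("read_distance_table: expected 2 value rows in ", path)
  if (length(pairs) == 0)
    return(data.frame(pair = character(0), euclidean = numeric(0),
                      gap_measure = numeric(0)))
  eu <- as.numeric(cells[[2]][-1])
  gm <- as.numeric(cells[[3]][-1])
  data.frame(pair = pairs, euclidean = eu, gap_measure = gm,
             stringsAsFactors = FALSE)
}
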