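# full-precision numeric formatting so CSV round trips are lossless
.format_numeric_cols <- function(df) {
  df[] <- lapply(df, function(col)
    if (is.numeric(col)) sprintf("%.17g", col) else col)
  df
}

.read_checked_csv <- function(path, required) {
  df <- utils::read.csv(path, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("file '%s' is missing required column(s): %s",
                 path, paste(miss, collapse = ", ")))
  for (col in required) {
    if (!is.numeric(df[[col]]))
      stop(sprintf("column '%s' in '%s' is not numeric", col, path))
    df[[col]] <- as.double(df[[col]])
  }
  df
}

#' Read / write fluorometry traces
#'
#' Plain CSV with a header row, '.' decimals, and unit-suffixed column
#' names `time_ms`, `fluorescence`, `voltage_mV`. Numerics are written with
#' 17 significant digits so a write/read round trip reproduces the values
#' exactly; unknown extra columns are preserved.
#'
#' @param path file path.
#' @param trace data frame with the required columns.
#' @return `read_trace` returns a data frame; `write_trace` returns `path`
#'   invisibly.
#' @export
read_trace <- function(path) {
  .read_checked_csv(path, c("time_ms", "fluorescence", "voltage_mV"))
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  need <- c("time_ms", "fluorescence", "voltage_mV")
  miss <- setdiff(need, names(trace))
  if (length(miss))
    stop("trace is missing required column(s): ", paste(miss, collapse = ", "))
  utils::write.table(.format_numeric_cols(as.data.frame(trace)), path,
                     sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write TCSPC histograms
#'
#' Plain CSV with columns `time_ns`, `counts`; counts must be non-negative.
#'
#' @param path file path.
#' @param hist a [decay_histogram()] (or data frame with the columns).
#' @return `read_histogram` returns a [decay_histogram()];
#'   `write_histogram` returns `path` invisibly.
#' @export
read_histogram <- function(path) {
  df <- .read_checked_csv(path, c("time_ns", "counts"))
  if (any(df$counts < 0))
    stop(sprintf("file '%s' contains negative counts", path))
  decay_histogram(df$time_ns, df$counts)
}

#' @rdname read_histogram
#' @export
write_histogram <- function(hist, path) {
  need <- c("time_ns", "counts")
  miss <- setdiff(need, names(hist))
  if (length(miss))
    stop("histogram is missing required column(s): ", paste(miss, collapse = ", "))
  utils::write.table(.format_numeric_cols(as.data.frame(unclass(hist))[need]),
                     path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a quenching curve
#'
#' CSV with columns `distance_A`, `p_inner`, `p_outer`, `dff_norm`.
#'
#' @param curve a [quench_curve()].
#' @param path file path.
#' @return `write_quench_curve` returns `path` invisibly;
#'   `read_quench_curve` a plain data frame (the generating system is not
#'   stored in the file).
#' @export
write_quench_curve <- function(curve, path) {
  stopifnot(inherits(curve, "quench_curve"))
  utils::write.table(.format_numeric_cols(as.data.frame(curve)), path,
                     sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_quench_curve
#' @export
read_quench_curve <- function(path) {
  .read_checked_csv(path, c("distance_A", "p_inner", "p_outer", "dff_norm"))
}

#' Alpha-carbon distance between two residues of a PDB structure
#'
#' Euclidean distance between the C-alpha atoms of two residues in the
#' named chain (author residue numbering), reported to 0.1 Angstrom. Used
#' for reference distances against which FRET-derived axial estimates can
#' be compared.
#'
#' @param pdb_file path to a PDB-format file.
#' @param chain chain identifier.
#' @param res_a,res_b residue numbers.
#' @return Distance in Angstrom, rounded to 0.1.
#' @export
ca_distance <- function(pdb_file, chain, res_a, res_b) {
  if (!file.exists(pdb_file)) stop("PDB file not found: ", pdb_file)
  pdb <- bio3d::read.pdb(pdb_file)
  get_ca <- function(resno) {
    sel <- pdb$atom$chain == chain & pdb$atom$resno == resno &
      pdb$atom$elety == "CA"
    if (!any(sel))
      stop(sprintf("no C-alpha atom for residue %d in chain %s", resno, chain))
    as.numeric(pdb$atom[which(sel)[1], c("x", "y", "z")])
  }
  a <- get_ca(res_a)
  b <- get_ca(res_b)
  round(sqrt(sum((a - b)^2)), 1)
}
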