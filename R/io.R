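# Readers and writers: FASTA/FASTQ in, HDF5 profile container and TSV
# distance matrix out.

.CONTAINER_FORMAT <- "kmer-profile-v1"

#' Read sequence records from a FASTA file
#'
#' @param path path to a FASTA file (multi-line sequences allowed;
#'   transparently gunzipped if the name ends in .gz). An empty file
#'   yields an empty vector, not an error.
#' @return named character vector: names are the header lines (without
#'   ">"), values the sequences with whitespace removed and case
#'   preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) return(stats::setNames(character(0), character(0)))
  s <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(s), names(s))
}

#' Write sequence records to a FASTA file
#'
#' @param x named character vector of sequences (names become headers).
#' @param path output path.
#' @return `invisible(path)`.
#' @export
write_fasta <- function(x, path) {
  if (!is.character(x)) stop("x must be a character vector")
  s <- Biostrings::BStringSet(x)
  if (is.null(names(x))) names(s) <- paste0("seq", seq_along(x))
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' Convert FASTQ to FASTA
#'
#' Identifiers and sequences are preserved, base qualities discarded.
#' FASTA is the canonical input for profile counting; this is the
#' conversion path for read data.
#'
#' @param source path to a FASTQ file (4 lines per record).
#' @param sink output FASTA path.
#' @return number of records converted, invisibly also written to `sink`.
#' @export
fastq_to_fasta <- function(source, sink) {
  n_lines <- length(readLines(source))
  if (n_lines %% 4 != 0)
    stop("truncated FASTQ: ", n_lines, " lines is not a multiple of 4", call. = FALSE)
  s <- Biostrings::readBStringSet(source, format = "fastq")
  Biostrings::writeXStringSet(s, sink)
  length(s)
}

# open container, creating layout on first use
.container_init <- function(path) {
  if (!file.exists(path)) {
    rhdf5::h5createFile(path)
    fid <- rhdf5::H5Fopen(path)
    rhdf5::h5writeAttribute(.CONTAINER_FORMAT, fid, "format")
    rhdf5::H5Fclose(fid)
    rhdf5::h5createGroup(path, "profiles")
  }
  .container_check(path)
}

.container_check <- function(path) {
  if (!file.exists(path)) stop("no such container: ", path, call. = FALSE)
  fmt <- tryCatch(rhdf5::h5readAttributes(path, "/")$format, error = function(e) NULL)
  if (is.null(fmt) || !identical(as.character(fmt), .CONTAINER_FORMAT))
    stop("not a ", .CONTAINER_FORMAT, " container: ", path, call. = FALSE)
  invisible(path)
}

#' List profiles stored in a container
#'
#' @param path path to a profile container (HDF5; root attribute
#'   `format = "kmer-profile-v1"`, one dataset per profile under group
#'   `profiles`, each carrying `k` and `label` attributes).
#' @return character vector of profile names.
#' @export
list_profiles <- function(path) {
  .container_check(path)
  ls <- rhdf5::h5ls(path)
  ls$name[ls$group == "/profiles" & ls$otype == "H5I_DATASET"]
}

#' Save a profile into a container
#'
#' @param path container path; created (with the v1 layout) if absent.
#' @param p a [kmer_profile()].
#' @param name dataset name within the container; defaults to the
#'   profile's label. Names must be unique unless `overwrite`.
#' @param overwrite replace an existing profile of the same name.
#' @return `invisible(path)`.
#' @export
save_profile <- function(path, p, name = p$label, overwrite = FALSE) {
  .check_profile(p)
  .container_init(path)
  dset <- paste0("profiles/", name)
  if (name %in% list_profiles(path)) {
    if (!overwrite) stop("profile '", name, "' already exists (use overwrite = TRUE)",
                         call. = FALSE)
    rhdf5::h5delete(path, dset)
  }
  rhdf5::h5write(p$counts, path, dset)
  fid <- rhdf5::H5Fopen(path)
  did <- rhdf5::H5Dopen(fid, dset)
  rhdf5::h5writeAttribute(as.integer(p$k), did, "k")
  rhdf5::h5writeAttribute(p$label, did, "label")
  rhdf5::h5writeAttribute("A=00,C=01,G=10,T=11", did, "encoding")
  rhdf5::H5Dclose(did)
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Load a profile from a container
#'
#' @param path container path.
#' @param name profile name (see [list_profiles()]).
#' @return a [kmer_profile()]; integer counts round-trip exactly.
#' @export
load_profile <- function(path, name) {
  .container_check(path)
  if (!name %in% list_profiles(path))
    stop("no profile named '", name, "' in ", path, call. = FALSE)
  dset <- paste0("profiles/", name)
  counts <- as.numeric(rhdf5::h5read(path, dset))
  at <- rhdf5::h5readAttributes(path, dset)
  kmer_profile(counts, as.integer(at$k), as.character(at$label))
}

#' Write a distance matrix as TSV
#'
#' Line 1 holds the tab-separated labels; each following line holds a
#' label and the full row of values at 9 significant digits. The full
#' square symmetric matrix is written (self-describing, diff-friendly).
#'
#' @param m a `kmer_distmat` or labelled symmetric matrix.
#' @param path output path.
#' @return `invisible(path)`.
#' @export
write_matrix <- function(m, path) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("m must be a square matrix")
  labels <- rownames(m) %||% paste0("sample", seq_len(nrow(m)))
  rows <- vapply(seq_len(nrow(m)), function(i)
    paste(c(labels[i], formatC(m[i, ], digits = 9, format = "g")), collapse = "\t"),
    character(1))
  writeLines(c(paste(labels, collapse = "\t"), rows), path)
  invisible(path)
}

#' Read a distance matrix written by [write_matrix()]
#'
#' @param path TSV path.
#' @return a `kmer_distmat` matrix. Asymmetric or non-square input is an
#'   error.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("malformed matrix file: ", path, call. = FALSE)
  labels <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  n <- length(labels)
  if (length(lines) != n + 1) stop("matrix file has wrong number of rows", call. = FALSE)
  m <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    fields <- strsplit(lines[i + 1], "\t", fixed = TRUE)[[1]]
    if (length(fields) != n + 1) stop("row ", i, " has wrong length", call. = FALSE)
    vals <- suppressWarnings(as.numeric(fields[-1]))
    if (anyNA(vals)) stop("non-numeric value in row ", i, call. = FALSE)
    m[i, ] <- vals
  }
  if (max(abs(m - t(m))) > 1e-6) stop("matrix is not symmetric", call. = FALSE)
  structure(m, class = c("kmer_distmat", "matrix", "array"))
}
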