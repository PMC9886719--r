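#' Structural connectome objects
#'
#' A `connectome` holds one subject-timepoint's weighted, symmetric,
#' nonnegative parcel-by-parcel structural connectivity matrix (streamline
#' counts between atlas parcels). Parcels are identified by 1-based integer
#' ids and the matrix is stored in id-sorted order so node indexing is
#' deterministic regardless of file order. Self-connections are discarded:
#' a nonzero diagonal is zeroed on construction with a warning, since the
#' controllability formulation assumes no self-loops.
#'
#' @param W numeric n x n matrix of nonnegative edge weights.
#' @param parcel_ids integer vector of unique 1-based parcel ids, one per
#'   row/column of `W`.
#' @param subject_id opaque subject identifier.
#' @param timepoint `"T1"` or `"T2"`.
#' @param sym_tol absolute symmetry tolerance; asymmetry beyond it is an
#'   error (tractography count matrices should be exactly symmetric).
#' @return an object of class `connectome` with elements `subject_id`,
#'   `timepoint`, `parcel_ids`, and `W` (dimnames = parcel ids).
#' @export
connectome <- function(W, parcel_ids = seq_len(nrow(W)), subject_id = "S1",
                       timepoint = c("T1", "T2"), sym_tol = 1e-8) {
  timepoint <- match.arg(timepoint)
  W <- as.matrix(W)
  if (!is.numeric(W) || nrow(W) != ncol(W)) {
    stop("W must be a square numeric matrix")
  }
  if (any(!is.finite(W))) stop("W contains non-finite entries")
  parcel_ids <- as.integer(parcel_ids)
  n <- nrow(W)
  if (length(parcel_ids) != n) {
    stop("parcel_ids length must match matrix dimension")
  }
  if (anyDuplicated(parcel_ids)) stop("parcel_ids must be unique")
  if (any(parcel_ids < 1)) stop("parcel ids are 1-based positive integers")
  if (max(abs(W - t(W))) > sym_tol) {
    stop("asymmetric connectivity matrix (tolerance ", format(sym_tol), ")")
  }
  W <- (W + t(W)) / 2 # remove sub-tolerance asymmetry
  if (any(W < 0)) stop("negative edge weight")
  if (any(diag(W) != 0)) {
    warning("nonzero diagonal (self-connections) zeroed on load")
    diag(W) <- 0
  }
  ord <- order(parcel_ids)
  parcel_ids <- parcel_ids[ord]
  W <- W[ord, ord, drop = FALSE]
  dimnames(W) <- list(parcel_ids, parcel_ids)
  structure(
    list(subject_id = subject_id, timepoint = timepoint,
         parcel_ids = parcel_ids, W = W),
    class = "connectome"
  )
}

#' @exportS3Method base::print
print.connectome <- function(x, ...) {
  cat(sprintf(
    "connectome: subject %s, %s, %d parcels, %d edges, total weight %g\n",
    x$subject_id, x$timepoint, length(x$parcel_ids),
    sum(x$W[upper.tri(x$W)] > 0), sum(x$W) / 2
  ))
  invisible(x)
}

# -- file formats -------------------------------------------------------------
#
# Both on-disk formats are TSV with optional leading metadata comment lines
#   #subject_id: S1
#   #timepoint: T1
#   #parcel_ids: 1 2 3        (edge list only; dense carries ids in its header)
# Dense: header row of parcel ids, then n matrix rows.
# Edge list: header "parcel_i\tparcel_j\tweight", one row per unordered
# nonzero pair; unlisted pairs are implicitly zero.

read_meta_lines <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (l in lines[is_meta]) {
    m <- regmatches(l, regexec("^#([a-z_]+):\\s*(.*)$", l))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  list(meta = meta, body = lines[!is_meta])
}

#' Read a structural connectome from disk
#'
#' @param path file path.
#' @param format `"dense"` (header of parcel ids + matrix rows) or
#'   `"edgelist"` (columns parcel_i, parcel_j, weight; unlisted pairs are
#'   zero; entries given in either order are merged, conflicting duplicates
#'   are an error).
#' @param subject_id,timepoint overrides for the file's metadata lines
#'   (default subject "S1", timepoint "T1" when absent).
#' @param parcel_ids full parcel universe for edge-list files whose isolated
#'   parcels appear in no edge; defaults to the file's `#parcel_ids`
#'   metadata, falling back to the ids observed in the edges.
#' @return a validated [connectome].
#' @export
read_connectome <- function(path, format = c("dense", "edgelist"),
                            subject_id = NULL, timepoint = NULL,
                            parcel_ids = NULL) {
  format <- match.arg(format)
  parsed <- read_meta_lines(path)
  subject_id <- subject_id %||% parsed$meta$subject_id %||% "S1"
  timepoint <- timepoint %||% parsed$meta$timepoint %||% "T1"
  body <- parsed$body
  if (length(body) == 0) stop("empty connectome file: ", path)
  if (format == "dense") {
    header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
    ids <- suppressWarnings(as.integer(header))
    if (any(is.na(ids))) stop("dense header must be integer parcel ids")
    n <- length(ids)
    if (length(body) - 1 != n) {
      stop("non-square dense input: ", n, " columns but ",
           length(body) - 1, " data rows")
    }
    rows <- lapply(body[-1], function(l) {
      v <- suppressWarnings(as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]]))
      if (length(v) != n || any(is.na(v))) {
        stop("malformed dense matrix row (expected ", n, " numeric fields)")
      }
      v
    })
    W <- do.call(rbind, rows)
    return(connectome(W, ids, subject_id = subject_id, timepoint = timepoint))
  }
  # edge list
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, c("parcel_i", "parcel_j", "weight"))) {
    stop("edge list header must be 'parcel_i\\tparcel_j\\tweight'")
  }
  edges <- if (length(body) > 1) {
    do.call(rbind, lapply(body[-1], function(l) {
      v <- strsplit(l, "\t", fixed = TRUE)[[1]]
      if (length(v) != 3) stop("malformed edge row: ", l)
      v
    }))
  } else {
    matrix(character(0), ncol = 3)
  }
  ei <- suppressWarnings(as.integer(edges[, 1]))
  ej <- suppressWarnings(as.integer(edges[, 2]))
  w <- suppressWarnings(as.numeric(edges[, 3]))
  if (any(is.na(ei)) || any(is.na(ej))) stop("non-integer parcel id in edge list")
  if (any(is.na(w))) stop("non-numeric weight in edge list")
  if (is.null(parcel_ids) && !is.null(parsed$meta$parcel_ids)) {
    parcel_ids <- as.integer(strsplit(parsed$meta$parcel_ids, " ", fixed = TRUE)[[1]])
  }
  ids <- sort(unique(c(as.integer(parcel_ids), ei, ej)))
  if (length(ids) == 0) stop("edge list defines no parcels")
  n <- length(ids)
  idx <- function(p) match(p, ids)
  W <- matrix(0, n, n)
  if (length(ei) > 0) {
    lo <- pmin(ei, ej)
    hi <- pmax(ei, ej)
    key <- paste(lo, hi)
    for (k in unique(key)) {
      wk <- unique(w[key == k])
      if (length(wk) > 1) {
        stop("duplicate conflicting edge list entries for pair ", k)
      }
    }
    keep <- !duplicated(key)
    W[cbind(idx(lo[keep]), idx(hi[keep]))] <- w[keep]
    W[cbind(idx(hi[keep]), idx(lo[keep]))] <- w[keep]
  }
  connectome(W, ids, subject_id = subject_id, timepoint = timepoint)
}

#' Write a connectome to disk
#'
#' Round-trip contract: `read_connectome(write_matrix(C, ...), ...)` equals
#' `C` exactly for integer weights (metadata comment lines preserve the
#' subject id, timepoint, and — for edge lists — the full parcel universe,
#' so isolated parcels survive the round trip).
#'
#' @param C a [connectome].
#' @param path output file path.
#' @param format `"dense"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(C, path, format = c("dense", "edgelist")) {
  format <- match.arg(format)
  stopifnot(inherits(C, "connectome"))
  num <- function(x) {
    # exact for integers, full precision otherwise
    ifelse(x == round(x), sprintf("%d", as.integer(round(x))),
           formatC(x, digits = 17, format = "g"))
  }
  meta <- c(
    paste0("#subject_id: ", C$subject_id),
    paste0("#timepoint: ", C$timepoint)
  )
  if (format == "dense") {
    lines <- c(
      meta,
      paste(C$parcel_ids, collapse = "\t"),
      apply(C$W, 1, function(r) paste(num(r), collapse = "\t"))
    )
  } else {
    ut <- which(upper.tri(C$W) & C$W > 0, arr.ind = TRUE)
    lines <- c(
      meta,
      paste0("#parcel_ids: ", paste(C$parcel_ids, collapse = " ")),
      "parcel_i\tparcel_j\tweight",
      if (nrow(ut) > 0) {
        paste(C$parcel_ids[ut[, 1]], C$parcel_ids[ut[, 2]],
              num(C$W[ut]), sep = "\t")
      }
    )
  }
  con <- file(path, open = "wb") # bytewise-deterministic output
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
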