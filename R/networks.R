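#' Atlas network-membership tables
#'
#' A `network_definition` maps 1-based parcel ids to named networks
#' (e.g. the frontoparietal `"control"` network and the
#' `"multiple_demand"` system). One row per (parcel, network) membership;
#' a parcel may belong to several networks — frontoparietal parcels belong
#' to both networks of interest.
#'
#' @param table data.frame with integer `parcel_id`, character
#'   `parcel_name`, character `network_label`.
#' @return object of class `network_definition` (a validated data.frame).
#' @export
network_definition <- function(table) {
  req <- c("parcel_id", "parcel_name", "network_label")
  if (!all(req %in% names(table))) {
    stop("network definition needs columns: ", paste(req, collapse = ", "))
  }
  if (nrow(table) == 0) stop("empty network definition")
  pid <- table$parcel_id
  if (is.character(pid)) {
    pid_int <- suppressWarnings(as.integer(pid))
    if (any(is.na(pid_int)) || any(pid_int != as.numeric(pid))) {
      stop("non-integer parcel_id in network definition")
    }
    pid <- pid_int
  }
  if (any(is.na(pid)) || any(pid != round(pid)) || any(pid < 1)) {
    stop("non-integer parcel_id in network definition")
  }
  table$parcel_id <- as.integer(pid)
  table$network_label <- as.character(table$network_label)
  table$parcel_name <- as.character(table$parcel_name)
  if (anyDuplicated(table[, c("parcel_id", "network_label")])) {
    stop("duplicate (parcel_id, network_label) pair")
  }
  structure(table[, req], class = c("network_definition", "data.frame"))
}

#' Read a network membership table (TSV: parcel_id, parcel_name,
#' network_label). Repeated parcel_id rows with different labels accumulate
#' into overlapping memberships.
#'
#' @param path file path.
#' @return a [network_definition].
#' @export
read_network_definition <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) < 2) stop("empty network definition file: ", path)
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           colClasses = "character")
  network_definition(tab)
}

#' Member parcels of a named network
#'
#' @param D a [network_definition].
#' @param network network label.
#' @return sorted integer vector of member parcel ids.
#' @export
network_members <- function(D, network) {
  stopifnot(inherits(D, "network_definition"))
  ids <- D$parcel_id[D$network_label == network]
  if (length(ids) == 0) stop("network '", network, "' has no members")
  sort(unique(ids))
}

#' @exportS3Method base::print
print.network_definition <- function(x, ...) {
  tab <- table(x$network_label)
  cat("network_definition:", length(unique(x$parcel_id)), "parcels;",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Write a network definition as TSV
#' @param D a [network_definition].
#' @param path output path.
#' @export
write_network_definition <- function(D, path) {
  stopifnot(inherits(D, "network_definition"))
  lines <- c(
    "parcel_id\tparcel_name\tnetwork_label",
    paste(D$parcel_id, D$parcel_name, D$network_label, sep = "\t")
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
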