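# Dataset layer: NONMEM-style flat table
#   ID    subject id
#   TIME  days since first infusion
#   AMT   dose amount (mg), dose rows only
#   DV    observed CD19+ B-cell count (cells/uL), observation rows only
#   EVID  1 = dose, 0 = observation
#   MDV   1 = DV missing/ignored
#   plus covariate columns (IGA in g/L, BSA in m2, ...), constant within ID.

.kpd_required_cols <- c("ID", "TIME", "AMT", "DV", "EVID", "MDV")

#' Validate a K-PD dataset
#'
#' Checks the NONMEM-style layout: required columns, non-negative times,
#' dose rows with positive AMT, exactly one of AMT/DV meaningful per row,
#' no duplicate (ID, TIME, EVID) rows, covariates constant within subject,
#' and at least one dose per subject.  Errors name offending rows.
#'
#' @param data a data frame.
#' @return the data (invisibly), with covariate columns identified in
#'   attribute \code{"covariates"}.
#' @export
validate_kpd_data <- function(data) {
  data <- as.data.frame(data)
  miss <- setdiff(.kpd_required_cols, names(data))
  if (length(miss)) {
    stop_kpd("dataset is missing required columns: ",
             paste(miss, collapse = ", "), class = "kpd_data_error")
  }
  if (nrow(data) == 0L) stop_kpd("dataset is empty", class = "kpd_data_error")
  bad <- which(!data$EVID %in% c(0L, 1L))
  if (length(bad)) {
    stop_kpd("EVID must be 0 or 1; rows ", paste(head(bad, 5), collapse = ", "),
             class = "kpd_data_error")
  }
  bad <- which(!is.finite(data$TIME) | data$TIME < 0)
  if (length(bad)) {
    stop_kpd("TIME must be non-negative; rows ",
             paste(head(bad, 5), collapse = ", "), class = "kpd_data_error")
  }
  bad <- which(data$EVID == 1L & (!is.finite(data$AMT) | data$AMT <= 0))
  if (length(bad)) {
    stop_kpd("dose rows (EVID=1) need positive AMT; rows ",
             paste(head(bad, 5), collapse = ", "), class = "kpd_data_error")
  }
  bad <- which(data$EVID == 0L & data$MDV != 1L &
                 !is.finite(as.numeric(data$DV)))
  if (length(bad)) {
    stop_kpd("observation rows (EVID=0, MDV=0) need numeric DV; rows ",
             paste(head(bad, 5), collapse = ", "), class = "kpd_data_error")
  }
  key <- paste(data$ID, data$TIME, data$EVID)
  if (anyDuplicated(key)) {
    stop_kpd("duplicate (ID, TIME, EVID) rows: ",
             paste(head(which(duplicated(key)), 5), collapse = ", "),
             class = "kpd_data_error")
  }
  covs <- setdiff(names(data), .kpd_required_cols)
  for (cv in covs) {
    nuniq <- tapply(data[[cv]], data$ID, function(x) length(unique(x)))
    if (any(nuniq > 1)) {
      stop_kpd("covariate '", cv, "' varies within subject(s) ",
               paste(head(names(nuniq)[nuniq > 1], 5), collapse = ", "),
               class = "kpd_data_error")
    }
  }
  nodose <- tapply(data$EVID, data$ID, function(e) !any(e == 1L))
  if (any(nodose)) {
    stop_kpd("subject(s) without any dose row: ",
             paste(head(names(nodose)[nodose], 5), collapse = ", "),
             class = "kpd_data_error")
  }
  attr(data, "covariates") <- covs
  invisible(data)
}

#' Read a K-PD dataset from CSV
#'
#' @param path CSV file with the NONMEM-style header (comma separated, dot
#'   decimal).  Empty DV/AMT cells are allowed on rows where they are not
#'   meaningful.
#' @return validated data frame.
#' @export
read_kpd_data <- function(path) {
  data <- read.csv(path, stringsAsFactors = FALSE)
  for (cl in intersect(c("TIME", "AMT", "DV"), names(data))) {
    data[[cl]] <- as.numeric(data[[cl]])
  }
  validate_kpd_data(data)
  data
}

#' Write a K-PD dataset to CSV
#'
#' Inverse of [read_kpd_data()]: stable column order (required columns first,
#' covariates after, alphabetically), deterministic formatting.
#'
#' @param data validated dataset.
#' @param path output path.
#' @export
write_kpd_data <- function(data, path) {
  validate_kpd_data(data)
  covs <- sort(setdiff(names(data), .kpd_required_cols))
  data <- data[c(.kpd_required_cols, covs)]
  write.csv(data, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# split a validated dataset into per-subject structures
kpd_split <- function(data) {
  data <- validate_kpd_data(data)
  covs <- attr(data, "covariates")
  ids <- unique(data$ID)
  lapply(ids, function(id) {
    d <- data[data$ID == id, , drop = FALSE]
    obs <- d[d$EVID == 0L, , drop = FALSE]
    dos <- d[d$EVID == 1L, , drop = FALSE]
    list(id = id,
         doses = data.frame(time = dos$TIME, amount = dos$AMT),
         obs = data.frame(time = obs$TIME, dv = as.numeric(obs$DV),
                          mdv = as.integer(obs$MDV)),
         covariates = if (length(covs))
           as.data.frame(d[1, covs, drop = FALSE], row.names = NULL)
         else data.frame(row.names = 1L))
  })
}

# flatten subjects back into the estimation arrays used by the C++ kernel;
# missing observations (MDV=1) are dropped from the likelihood here
kpd_flatten <- function(subjects) {
  obs <- lapply(subjects, function(s) s$obs[s$obs$mdv == 0L, , drop = FALSE])
  olen <- vapply(obs, nrow, integer(1))
  dlen <- vapply(subjects, function(s) nrow(s$doses), integer(1))
  list(
    obs_start = c(0L, cumsum(olen))[seq_along(subjects)],
    obs_len = olen,
    obs_t = unlist(lapply(obs, `[[`, "time"), use.names = FALSE) %||% numeric(0),
    obs_y = unlist(lapply(obs, `[[`, "dv"), use.names = FALSE) %||% numeric(0),
    dose_start = c(0L, cumsum(dlen))[seq_along(subjects)],
    dose_len = dlen,
    dose_t = unlist(lapply(subjects, function(s) s$doses$time),
                    use.names = FALSE),
    dose_a = unlist(lapply(subjects, function(s) s$doses$amount),
                    use.names = FALSE),
    covariates = do.call(rbind, lapply(subjects, `[[`, "covariates")),
    ids = vapply(subjects, function(s) as.character(s$id), character(1))
  )
}
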