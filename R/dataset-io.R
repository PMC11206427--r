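#' @useDynLib voripopk, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median optim quantile rbinom rlnorm rnorm runif sd
#'   setNames qlogis plogis cor qnorm pnorm integrate
#' @importFrom utils read.csv write.csv
NULL

# Lower limit of quantification of the voriconazole assay (mg/L);
# observations below it are flagged BLQ and excluded from estimation (M1).
VORI_LLOQ <- 0.097

#' Assay lower limit of quantification
#'
#' @return The LLOQ in mg/L below which observations are flagged as BLQ.
#' @export
vori_lloq <- function() VORI_LLOQ

ROUTE_LEVELS <- c("iv", "oral", "ng")

STD_COLS <- c("ID", "TIME", "EVID", "AMT", "DUR", "ROUTE", "SS", "II",
              "DV", "MDV", "BLQ", "OCC")

#' Construct an event dataset
#'
#' An event dataset is a NONMEM-style long table: one row per dose event
#' (`EVID = 1`) or observation event (`EVID = 0`), with occasion-varying
#' covariates carried on every row. Covariate columns are all lower-case
#' non-standard columns.
#'
#' @param events Data frame with at least `ID`, `TIME`, `EVID`, `AMT`, `DV`,
#'   `MDV` and for doses `ROUTE`/`DUR` (or `SS`/`II` for steady-state
#'   records).
#' @param source Provenance string.
#' @param seed Seed used if the data are synthetic, else `NA`.
#' @param truth Optional list with the generating model and per-subject etas
#'   (synthetic data only).
#' @return Object of class `pk_dataset`.
#' @export
pk_dataset <- function(events, source = "constructed", seed = NA_integer_,
                       truth = NULL) {
  stopifnot(is.data.frame(events))
  needed <- c("ID", "TIME", "EVID")
  miss <- setdiff(needed, names(events))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  for (cc in setdiff(STD_COLS, names(events))) {
    events[[cc]] <- rep(switch(cc,
      AMT = 0, DUR = NA_real_, ROUTE = NA_character_, SS = 0L, II = NA_real_,
      DV = NA_real_, MDV = 1L, BLQ = 0L, OCC = 1L), nrow(events))
  }
  events$ID <- as.character(events$ID)
  obs <- events$EVID == 0 & events$MDV == 0
  events$BLQ[obs] <- as.integer(events$DV[obs] < VORI_LLOQ)
  structure(list(events = events[c(STD_COLS, setdiff(names(events), STD_COLS))],
                 source = source, seed = seed, truth = truth),
            class = "pk_dataset")
}

#' @export
print.pk_dataset <- function(x, ...) {
  ev <- x$events
  cat(sprintf("PK event dataset: %d subjects, %d dose events, %d observations (%d BLQ)\n",
              length(unique(ev$ID)), sum(ev$EVID == 1),
              sum(ev$EVID == 0 & ev$MDV == 0),
              sum(ev$BLQ == 1, na.rm = TRUE)))
  cat("  source:", x$source, if (!is.na(x$seed)) sprintf("(seed %d)", x$seed), "\n")
  invisible(x)
}

#' Number of subjects / observations
#' @param ds A `pk_dataset`.
#' @return Integer count.
#' @export
n_subjects <- function(ds) length(unique(ds$events$ID))

#' @rdname n_subjects
#' @export
n_observations <- function(ds) sum(ds$events$EVID == 0 & ds$events$MDV == 0)

#' Covariate column names of a dataset
#' @param ds A `pk_dataset`.
#' @return Character vector of covariate column names.
#' @export
covariate_names <- function(ds) setdiff(names(ds$events), STD_COLS)

normalise_route <- function(x, row = NULL) {
  out <- rep(NA_character_, length(x))
  chr <- tolower(trimws(as.character(x)))
  map <- c(iv = "iv", "1" = "iv", intravenous = "iv", iv_infusion = "iv",
           oral = "oral", po = "oral", "2" = "oral",
           ng = "ng", nasogastric = "ng", "3" = "ng")
  known <- chr %in% names(map)
  out[known] <- map[chr[known]]
  bad <- !known & !is.na(x) & chr != ""
  if (any(bad))
    stop("unknown route code '", chr[which(bad)[1]], "'",
         if (!is.null(row)) paste0(" at row ", row[which(bad)[1]]))
  out
}

#' Read a NONMEM-style event CSV
#'
#' Expected columns: `ID`, `TIME`, `AMT`, `EVID`, `DV`, `MDV`, plus `DUR`
#' or `RATE` (infusion duration; `DUR` takes precedence, otherwise
#' `AMT/RATE`; 1 h assumed when neither is recorded), optional `SS`/`II`
#' steady-state fields, `ROUTE` (iv/oral/ng, or codes 1/2/3) and covariate
#' columns. `MDV = 1` rows carry no DV. Observations below the assay LLOQ
#' are flagged BLQ.
#'
#' @param path CSV file path.
#' @return A `pk_dataset`.
#' @export
read_pk_dataset <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  names(raw)[names(raw) %in% tolower(STD_COLS)] <-
    toupper(names(raw)[names(raw) %in% tolower(STD_COLS)])
  nm <- names(raw)
  for (req in c("ID", "TIME", "EVID"))
    if (!req %in% nm) stop("column '", req, "' missing from ", path)
  if (!"AMT" %in% nm) raw$AMT <- 0
  if (!"MDV" %in% nm) raw$MDV <- ifelse(raw$EVID == 0, 0L, 1L)
  if (!"DV" %in% nm) raw$DV <- NA_real_
  rown <- seq_len(nrow(raw)) + 1L # header offset for messages
  dose <- raw$EVID == 1
  badamt <- dose & (is.na(raw$AMT) | raw$AMT <= 0)
  if (any(badamt))
    stop("dose record with missing/zero AMT at row ", rown[which(badamt)[1]])
  if ("ROUTE" %in% nm) raw$ROUTE <- normalise_route(raw$ROUTE, rown)
  else raw$ROUTE <- ifelse(dose, "iv", NA_character_)
  if (!"DUR" %in% nm) raw$DUR <- NA_real_
  if ("RATE" %in% nm) {
    use <- dose & is.na(raw$DUR) & !is.na(raw$RATE) & raw$RATE > 0
    raw$DUR[use] <- raw$AMT[use] / raw$RATE[use]
    raw$RATE <- NULL
  }
  raw$DUR[dose & raw$ROUTE == "iv" & is.na(raw$DUR)] <- 1
  raw$DUR[dose & raw$ROUTE != "iv"] <- NA_real_
  raw$DV[raw$MDV == 1] <- NA_real_
  raw$CMT <- NULL
  # per-subject monotone times
  for (id in unique(raw$ID)) {
    tt <- raw$TIME[raw$ID == id]
    if (is.unsorted(tt))
      stop("non-monotone event times within subject ", id)
  }
  # a subject id must have consistent subject-level covariates
  for (cc in intersect(c("age", "weight", "sex"), tolower(nm))) {
    ccol <- nm[tolower(nm) == cc][1]
    agg <- tapply(raw[[ccol]], raw$ID, function(v) length(unique(v[!is.na(v)])))
    if (any(agg > 1))
      stop("duplicate subject id with conflicting '", cc, "' values: ",
           names(agg)[which(agg > 1)[1]])
  }
  names(raw) <- ifelse(names(raw) %in% STD_COLS, names(raw), tolower(names(raw)))
  pk_dataset(raw, source = path)
}

#' Write an event dataset to CSV
#'
#' Writes the canonical column layout read back by [read_pk_dataset()]
#' (round-trip identity on all fields).
#'
#' @param ds A `pk_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "pk_dataset"))
  write.csv(ds$events, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate an event dataset
#'
#' Pure reporting: checks structural rules (sorted non-negative times,
#' dose fields by route, 0/1 flags, covariates present at observation rows,
#' BLQ flag consistency, observations preceded by a dose) and returns a
#' violation table without touching the data.
#'
#' @param ds A `pk_dataset`.
#' @return Data frame with columns `severity` (`"error"`/`"warning"`),
#'   `subject`, `rule`, `message`; zero rows when the dataset is clean.
#' @export
validate_pk_dataset <- function(ds) {
  stopifnot(inherits(ds, "pk_dataset"))
  ev <- ds$events
  out <- list()
  add <- function(severity, subject, rule, message)
    out[[length(out) + 1L]] <<- data.frame(severity = severity,
                                           subject = subject, rule = rule,
                                           message = message)
  if (any(duplicated(unique(ev$ID)))) add("error", NA, "unique_ids", "duplicated ids")
  for (id in unique(ev$ID)) {
    sub <- ev[ev$ID == id, ]
    if (any(sub$TIME < 0))
      add("error", id, "time_nonneg", "negative event time")
    if (is.unsorted(sub$TIME))
      add("error", id, "time_sorted", "event times not sorted")
    doses <- sub[sub$EVID == 1, ]
    obs <- sub[sub$EVID == 0 & sub$MDV == 0, ]
    if (nrow(doses)) {
      iv <- doses$ROUTE == "iv"
      if (any(iv & (is.na(doses$DUR) | doses$DUR <= 0)))
        add("error", id, "iv_duration", "IV dose without positive duration")
      if (any(!iv & !is.na(doses$DUR)))
        add("error", id, "oral_duration", "extravascular dose carries a duration")
      if (any(doses$SS == 1 & (is.na(doses$II) | doses$II <= 0)))
        add("error", id, "ss_interval", "steady-state dose without interval")
      if (any(doses$AMT <= 0))
        add("error", id, "dose_amt", "non-positive dose amount")
    }
    if (nrow(obs)) {
      first_dose <- if (nrow(doses)) min(doses$TIME) else Inf
      early <- obs$TIME < first_dose
      if (any(early))
        add("warning", id, "obs_before_dose",
            sprintf("%d observation(s) before any dose", sum(early)))
      bad_blq <- xor(obs$DV < VORI_LLOQ, obs$BLQ == 1)
      if (any(bad_blq, na.rm = TRUE))
        add("error", id, "blq_flag", "BLQ flag inconsistent with LLOQ")
      for (cc in intersect(c("qcrp", "clcr", "plt", "pt"), covariate_names(ds))) {
        if (any(is.na(obs[[cc]]) | obs[[cc]] <= 0))
          add("error", id, paste0("cov_", cc),
              paste0("missing/non-positive ", cc, " at an observation"))
      }
      for (cc in intersect(c("crrt", "ecmo", "sex"), covariate_names(ds))) {
        bad <- !obs[[cc]] %in% c(0, 1)
        if (any(bad))
          add("error", id, paste0("flag_", cc),
              sprintf("%s value %s at occasion %s is not 0/1", cc,
                      obs[[cc]][which(bad)[1]], obs$OCC[which(bad)[1]]))
      }
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(severity = character(), subject = character(),
                  rule = character(), message = character())
}

#' Cockcroft-Gault creatinine clearance
#'
#' \deqn{CL_{CR} = \frac{(140 - age) \times weight}{72 \times S_{Cr}[mg/dL]}
#' \times 0.85^{female}}
#' with serum creatinine supplied in µmol/L and converted internally
#' (1 mg/dL = 88.4 µmol/L).
#'
#' @param age Age in years (0 < age < 140).
#' @param weight Body weight (kg).
#' @param scr Serum creatinine (µmol/L).
#' @param sex `"male"`/`"female"` or 0 (male) / 1 (female).
#' @return Creatinine clearance (mL/min).
#' @examples
#' cockcroft_gault(66, 65, 78.5, "male")
#' @export
cockcroft_gault <- function(age, weight, scr, sex) {
  if (is.character(sex) || is.factor(sex))
    sex <- match.arg(tolower(as.character(sex)), c("male", "female")) == "female"
  sex <- as.numeric(sex)
  if (any(age <= 0) || any(weight <= 0) || any(scr <= 0))
    stop("age, weight and serum creatinine must be positive")
  clcr <- ((140 - age) * weight) / (72 * (scr / 88.4)) * ifelse(sex == 1, 0.85, 1)
  if (any(clcr <= 0))
    stop("non-positive creatinine clearance (age >= 140?)")
  clcr
}

# ---- internal compiled representation for estimation -----------------------

# Split a pk_dataset into per-subject structures consumed by the likelihood
# kernel: non-BLQ observation times/values, the dose-event matrix, and the
# covariate values in effect at each observation row (LOCF is implicit:
# covariates are carried on the observation rows themselves).
compile_subjects <- function(ds, cov_names = character(), include_blq = FALSE) {
  ev <- ds$events
  ids <- unique(ev$ID)
  lapply(ids, function(id) {
    sub <- ev[ev$ID == id, ]
    doses <- sub[sub$EVID == 1, ]
    obs <- sub[sub$EVID == 0 & sub$MDV == 0, ]
    if (!include_blq) obs <- obs[obs$BLQ == 0, ]
    covm <- if (length(cov_names))
      as.matrix(obs[, cov_names, drop = FALSE]) else
      matrix(0, nrow(obs), 0)
    list(id = id,
         t = obs$TIME, y = obs$DV,
         n_blq = sum(sub$EVID == 0 & sub$MDV == 0 & sub$BLQ == 1),
         doses = data.frame(time = doses$TIME, amt = doses$AMT,
                            route = doses$ROUTE, tinf = doses$DUR,
                            ss = doses$SS, ii = doses$II),
         cov = covm)
  })
}
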