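# Plain-CSV readers for the assay inputs.  All readers return base data
# frames and validate the column contract; they never guess formats.

#' Read long-format spot-count data
#'
#' Expected columns: `sample_id`, `replicate_id`, `concentration` (mM),
#' `dilution_exponent` (0 ... -6), `count` (integer or the string `"TNTC"`
#' for spots too numerous to count).
#'
#' @param path CSV file path.
#' @param spot_volume Spot volume in mL applied to all series.
#' @return Nested list: concentration -> replicate -> [spot_series()].
#' @export
read_spot_csv <- function(path, spot_volume = 0.010) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "replicate_id", "concentration",
            "dilution_exponent", "count")
  if (!all(need %in% names(d))) {
    stop("spot CSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  cnt <- d$count
  cnt[cnt == "TNTC"] <- "Inf"
  d$count <- suppressWarnings(as.numeric(cnt))
  if (anyNA(d$count)) {
    stop("unparseable counts (use integers or \"TNTC\")", call. = FALSE)
  }
  concs <- sort(unique(d$concentration))
  out <- lapply(concs, function(cc) {
    sub <- d[d$concentration == cc, ]
    reps <- unique(sub$replicate_id)
    lapply(reps, function(r) {
      s <- sub[sub$replicate_id == r, ]
      s <- s[order(-s$dilution_exponent), ]
      spot_series(s$count, dilution_exponents = s$dilution_exponent,
                  spot_volume = spot_volume,
                  sample_id = s$sample_id[1], replicate_id = r)
    })
  })
  names(out) <- as.character(concs)
  out
}

#' Read competition event counts
#'
#' Expected columns: `sample`, `positives_t0`, `total_t0`, `positives_t1`,
#' `total_t1`, `expansion`.
#'
#' @param path CSV file path.
#' @return Data frame ready for [competition_fitness()].
#' @export
read_competition_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "positives_t0", "total_t0", "positives_t1",
            "total_t1", "expansion")
  if (!all(need %in% names(d))) {
    stop("competition CSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  d
}

#' Read an ITC heat table
#'
#' Expected columns: `injection`, `volume` (uL), `sample_heat`,
#' `blank_heat` (uJ).  Row 1 is taken as the throw-away injection.
#'
#' @param path CSV file path.
#' @param protocol The matching [itc_protocol()]; defaults are rebuilt from
#'   the table's volumes when `NULL`.
#' @return An `itc_experiment` list usable by [subtract_blank()].
#' @export
read_itc_csv <- function(path, protocol = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("injection", "volume", "sample_heat", "blank_heat")
  if (!all(need %in% names(d))) {
    stop("ITC CSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  d <- d[order(d$injection), ]
  if (is.null(protocol)) {
    protocol <- itc_protocol(n_injections = nrow(d),
                             injection_volume = d$volume[nrow(d)],
                             first_volume = d$volume[1])
  }
  structure(list(protocol = protocol, sample_heats = d$sample_heat,
                 blank_heats = d$blank_heat, units = "uJ"),
            class = "itc_experiment")
}

#' Read an MST dose-response table
#'
#' Expected columns: `concentration` (mM), `F_norm`; optional `replicate`.
#'
#' @param path CSV file path.
#' @return Data frame for [fit_hill()].
#' @export
read_mst_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("concentration", "F_norm") %in% names(d))) {
    stop("MST CSV needs columns concentration, F_norm", call. = FALSE)
  }
  d
}

#' Read a long-format growth-curve table
#'
#' Expected columns: `strain`, `concentration`, `replicate`, `time_h`,
#' `od600`.
#'
#' @param path CSV file path.
#' @return Data frame; split by strain/concentration/replicate before
#'   calling [fit_growth()].
#' @export
read_growth_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain", "concentration", "replicate", "time_h", "od600")
  if (!all(need %in% names(d))) {
    stop("growth CSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  d
}
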