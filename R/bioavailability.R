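# Relative bioavailability (RBA) from Caco-2 transwell transport assays.
#
# An assay applies intestinal digestive fluid (fluoride concentration c_iv,
# volume v_iv) to the apical chamber of a Caco-2 monolayer; after incubation
# the apical-side concentration c_av is measured. Apical depletion relative
# to the total fluoride in the digested food sample (concentration t_s, mass
# m_s) gives the bioavailable fraction:
#
#   RBA = (c_iv - c_av) * v_iv / (t_s * m_s)
#
# RBA is held as a fraction in [0, 1] everywhere inside the package and
# formatted as a percentage only at I/O boundaries.

#' Construct a transwell transport assay record
#'
#' @param assay_id assay identifier.
#' @param food food name.
#' @param roast_day roasting day of the sample (integer days, `>= 0`).
#' @param c_iv fluoride concentration of the digestive-fluid mixture applied
#'   to the apical chamber, mg/L.
#' @param c_av fluoride concentration recovered on the apical side after
#'   incubation, mg/L. May exceed `c_iv` in noisy data (see
#'   [relative_bioavailability()]).
#' @param v_iv volume of digestive-fluid mixture applied, L.
#' @param t_s total fluoride concentration of the food sample, mg/kg.
#' @param m_s mass of food sample in the digestion, kg.
#' @param dilution_ratio digestive fluid : buffer dilution, informational
#'   (the study protocol used `"1:4"`).
#' @param teer_ok logical monolayer-integrity QC flag (transepithelial
#'   electrical resistance acceptable). Failed records are excluded from
#'   summaries by default.
#' @return A list of class `transport_assay`.
#' @export
transport_assay <- function(assay_id, food, roast_day, c_iv, c_av, v_iv,
                            t_s, m_s, dilution_ratio = "1:4", teer_ok = TRUE) {
  check_nonnegative(c_iv, "c_iv")
  check_nonnegative(c_av, "c_av")
  check_positive(v_iv, "v_iv")
  check_positive(t_s, "t_s")
  check_positive(m_s, "m_s")
  check_nonnegative(roast_day, "roast_day")
  stopifnot(is.logical(teer_ok), length(teer_ok) == 1L)
  structure(
    list(assay_id = as.character(assay_id), food = as.character(food),
         roast_day = as.integer(roast_day), c_iv = c_iv, c_av = c_av,
         v_iv = v_iv, t_s = t_s, m_s = m_s,
         dilution_ratio = dilution_ratio, teer_ok = teer_ok),
    class = "transport_assay")
}

#' Relative bioavailability of one transport assay
#'
#' `(c_iv - c_av) * v_iv / (t_s * m_s)`, returned as a fraction. A negative
#' raw value (apparent apical gain, `c_av > c_iv`, expected from measurement
#' noise near zero absorption) is clamped to 0 with a warning; the raw value
#' is preserved in the `"raw"` attribute.
#'
#' @param assay a [transport_assay()], or anything with fields `c_iv`,
#'   `c_av`, `v_iv`, `t_s`, `m_s` (e.g. a one-row data frame).
#' @return RBA as a fraction in `[0, 1]`, with attribute `raw` holding the
#'   unclamped value.
#' @export
relative_bioavailability <- function(assay) {
  for (f in c("v_iv", "t_s", "m_s")) check_positive(assay[[f]], f)
  for (f in c("c_iv", "c_av")) check_nonnegative(assay[[f]], f)
  raw <- (assay$c_iv - assay$c_av) * assay$v_iv / (assay$t_s * assay$m_s)
  rba <- raw
  if (raw < 0) {
    warning(sprintf(
      "negative raw RBA (%.4g): c_av > c_iv (apparent apical gain); clamped to 0",
      raw), call. = FALSE)
    rba <- 0
  }
  structure(rba, raw = raw)
}

#' Bioavailable ("absorbed") fluoride concentration
#'
#' @param c_food total fluoride concentration of the food, mg/kg.
#' @param rba relative bioavailability as a fraction in `[0, 1]`.
#' @return `c_food * rba`, mg/kg.
#' @export
absorbed_concentration <- function(c_food, rba) {
  check_nonnegative(c_food, "c_food")
  check_fraction(rba, "rba")
  c_food * rba
}

#' Summarise transport assays per food and roasting stage
#'
#' Aggregates per-assay RBA values by arithmetic mean within each
#' `(food, roast_day)` group and pairs them with the mean total concentration
#' from the matching concentration records; the absorbed concentration is
#' mean concentration times mean RBA. Assays failing the TEER QC flag are
#' excluded unless `include_teer_failures = TRUE`.
#'
#' @param assays a list of [transport_assay()] records, or a data frame with
#'   the assay columns (`food`, `roast_day`, `c_iv`, `c_av`, `v_iv`, `t_s`,
#'   `m_s`, optionally `teer_ok`).
#' @param concentrations data frame of concentration records with columns
#'   `food`, `roast_day`, `concentration` (mg/kg); every assay group must
#'   have at least one matching row.
#' @param include_teer_failures keep assays with `teer_ok = FALSE`?
#' @return Data frame: `food`, `roast_day`, `rba` (fraction),
#'   `absorbed_mg_per_kg`, `n_assays`. Empty input gives an empty data frame.
#' @export
summarize_bioavailability <- function(assays, concentrations,
                                      include_teer_failures = FALSE) {
  adf <- assays_as_df(assays)
  empty <- data.frame(food = character(), roast_day = integer(),
                      rba = numeric(), absorbed_mg_per_kg = numeric(),
                      n_assays = integer())
  if (nrow(adf) == 0L) return(empty)
  if (!include_teer_failures && "teer_ok" %in% names(adf)) {
    adf <- adf[adf$teer_ok, , drop = FALSE]
    if (nrow(adf) == 0L) return(empty)
  }
  key <- function(d) paste(d$food, d$roast_day, sep = "\r")
  missing_keys <- setdiff(unique(key(adf)), unique(key(concentrations)))
  if (length(missing_keys) > 0L) {
    stop("no concentration records for assay group(s): ",
         paste(gsub("\r", " day ", missing_keys), collapse = ", "),
         call. = FALSE)
  }
  adf$rba <- vapply(seq_len(nrow(adf)),
                    function(i) as.numeric(relative_bioavailability(adf[i, ])),
                    numeric(1))
  groups <- unique(adf[, c("food", "roast_day")])
  groups <- groups[order(groups$food, groups$roast_day), , drop = FALSE]
  out <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    in_g <- adf$food == g$food & adf$roast_day == g$roast_day
    c_g <- concentrations$concentration[
      concentrations$food == g$food & concentrations$roast_day == g$roast_day]
    rba <- mean(adf$rba[in_g])
    data.frame(food = g$food, roast_day = as.integer(g$roast_day), rba = rba,
               absorbed_mg_per_kg = mean(c_g) * rba,
               n_assays = sum(in_g))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

assays_as_df <- function(assays) {
  if (is.data.frame(assays)) return(assays)
  stopifnot(is.list(assays))
  if (length(assays) == 0L) {
    return(data.frame(food = character(), roast_day = integer()))
  }
  do.call(rbind, lapply(assays, function(a) {
    as.data.frame(unclass(a), stringsAsFactors = FALSE)
  }))
}
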