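#' Define a neighborhood variable
#'
#' A variable spec records how one tract-level variable is measured and how it
#' relates to adversity risk. `scale_type` distinguishes bounded percentages
#' (0-100) from non-negative rates (e.g., facilities per 10,000 residents).
#' `direction` is `"inverse"` when a higher raw value means *lower* expected
#' ACE exposure (e.g., greenspace, homeownership); such columns are flipped by
#' [orient_variables()] before any index construction.
#'
#' @param name Unique variable name.
#' @param scale_type `"percent"` (bounded 0-100) or `"rate"` (non-negative).
#' @param direction `"risk_aligned"` (higher = higher risk) or `"inverse"`.
#' @return A one-row `data.frame` with columns `name`, `scale_type`,
#'   `direction`.
#' @seealso [default_variable_specs()]
#' @export
variable_spec <- function(name,
                          scale_type = c("percent", "rate"),
                          direction = c("risk_aligned", "inverse")) {
  scale_type <- match.arg(scale_type)
  direction <- match.arg(direction)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  data.frame(name = name, scale_type = scale_type, direction = direction,
             stringsAsFactors = FALSE)
}

#' Default set of 25 neighborhood variables
#'
#' The default variable table mirrors the kinds of tract-level measures used
#' to characterize neighborhood environments in ACE research: demographic and
#' socioeconomic composition, food environment, healthcare access, health
#' status, alcohol access, crime, transit, and outdoor quality. Percent-type
#' variables are bounded in \[0, 100\]; rate-type variables are counts per
#' population and non-negative. Eight variables run opposite to adversity
#' risk (higher value = lower expected ACE exposure) and are flagged
#' `direction = "inverse"`.
#'
#' @return A 25-row `data.frame` of variable specs.
#' @export
default_variable_specs <- function() {
  spec <- function(name, scale_type, direction = "risk_aligned") {
    variable_spec(name, scale_type, direction)
  }
  do.call(rbind, list(
    spec("racial_ethnic_segregation", "percent"),
    spec("limited_english",           "percent"),
    spec("unemployment",              "percent"),
    spec("low_education",             "percent"),
    spec("poverty",                   "percent"),
    spec("homeownership",             "percent", "inverse"),
    spec("internet_access",           "percent", "inverse"),
    spec("marital_support",           "percent", "inverse"),
    spec("fast_food_access",          "rate",    "inverse"),
    spec("snap_retailer_access",      "rate"),
    spec("supermarket_low_access",    "percent"),
    spec("uninsured",                 "percent"),
    spec("health_center_access",      "rate"),
    spec("mental_healthcare_access",  "rate"),
    spec("sud_treatment_access",      "rate"),
    spec("depression_diagnosis",      "percent", "inverse"),
    spec("poor_mental_health",        "percent"),
    spec("poor_physical_health",      "percent"),
    spec("alcohol_access",            "rate"),
    spec("nonviolent_crime",          "rate"),
    spec("violent_crime",             "rate"),
    spec("traffic_burden",            "percent", "inverse"),
    spec("transit_access",            "rate",    "inverse"),
    spec("greenspace",                "percent", "inverse"),
    spec("air_quality",               "percent")
  ))
}

validate_specs <- function(specs) {
  stopifnot(is.data.frame(specs),
            all(c("name", "scale_type", "direction") %in% names(specs)))
  if (anyDuplicated(specs$name)) {
    stop("variable names must be unique: ",
         paste(unique(specs$name[duplicated(specs$name)]), collapse = ", "))
  }
  bad <- !specs$scale_type %in% c("percent", "rate")
  if (any(bad)) stop("unknown scale_type for: ",
                     paste(specs$name[bad], collapse = ", "))
  bad <- !specs$direction %in% c("risk_aligned", "inverse")
  if (any(bad)) stop("unknown direction for: ",
                     paste(specs$name[bad], collapse = ", "))
  invisible(specs)
}
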