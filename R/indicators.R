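#' Indicator specification
#'
#' An indicator specification describes one second-class indicator of the
#' supply or demand subsystem: its short code, which subsystem it belongs to,
#' its orientation (whether larger values mean more of the quantity the
#' subsystem measures, or less), and free-text label and unit.
#'
#' @param id Short indicator code, e.g. `"X5"` or `"Y2"`. Must be unique
#'   within a specification table.
#' @param subsystem `"supply"` or `"demand"`.
#' @param orientation `"positive"` (larger is more) or `"negative"`
#'   (larger is less); controls which min-max branch standardization uses.
#' @param label Human-readable description.
#' @param unit Measurement unit, free text.
#' @return A one-row data frame with columns `id`, `subsystem`,
#'   `orientation`, `label`, `unit`.
#' @seealso [elderly_care_indicators()] for the default 14-indicator system.
#' @export
indicator_spec <- function(id, subsystem = c("supply", "demand"),
                           orientation = c("positive", "negative"),
                           label = id, unit = "") {
  subsystem <- match.arg(subsystem)
  orientation <- match.arg(orientation)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  data.frame(id = id, subsystem = subsystem, orientation = orientation,
             label = label, unit = unit, stringsAsFactors = FALSE)
}

#' Combine indicator specifications into a specification table
#'
#' @param ... One-row data frames as returned by [indicator_spec()].
#' @return A data frame of indicator specifications with unique ids.
#' @export
indicator_set <- function(...) {
  spec <- do.call(rbind, list(...))
  if (anyDuplicated(spec$id))
    stop("duplicate indicator id(s): ",
         paste(unique(spec$id[duplicated(spec$id)]), collapse = ", "))
  rownames(spec) <- NULL
  spec
}

#' The elderly-care service resource index system
#'
#' The default 14-indicator system: ten supply-side indicators (X1-X10,
#' grouped in the source index system as human, material and financial
#' resources) and four demand-side indicators (Y1-Y4). All fourteen are
#' positive-orientation: larger values mean more supply capacity or more
#' demand pressure.
#'
#' @return A 14-row indicator specification table.
#' @examples
#' elderly_care_indicators()
#' @export
elderly_care_indicators <- function() {
  s <- function(id, label, unit)
    indicator_spec(id, "supply", "positive", label, unit)
  d <- function(id, label, unit)
    indicator_spec(id, "demand", "positive", label, unit)
  indicator_set(
    s("X1",  "Employees in pension institutions at year end",        "persons"),
    s("X2",  "Community service center employees at year end",       "persons"),
    s("X3",  "Number of pension institutions",                       "count"),
    s("X4",  "Number of beds for pension",                           "count"),
    s("X5",  "Building area of pension institutions",                "m2"),
    s("X6",  "Number of community pension institutions",             "count"),
    s("X7",  "Number of community day care beds",                    "count"),
    s("X8",  "Number of elderly receiving the old-age allowance",    "persons"),
    s("X9",  "Expenditure of welfare funds for the elderly",         "RMB million yuan"),
    s("X10", "Level of subsidy provided to ageing agencies",         "yuan/person/year"),
    d("Y1",  "Number of people aged over 65",                        "persons"),
    d("Y2",  "Elderly dependency ratio",                             "%"),
    d("Y3",  "Per capita disposable income",                         "yuan"),
    d("Y4",  "Elderly in pension institutions at year end",          "persons")
  )
}

#' The 31 province-level regions of mainland China
#'
#' Ordered region names matching the package's contiguity fixture and the
#' coupling-coordination reference tables.
#'
#' @return A character vector of length 31.
#' @export
china_regions <- function() {
  c("Beijing", "Tianjin", "Hebei", "Shanxi", "Inner Mongolia", "Liaoning",
    "Jilin", "Heilongjiang", "Shanghai", "Jiangsu", "Zhejiang", "Anhui",
    "Fujian", "Jiangxi", "Shandong", "Henan", "Hubei", "Hunan", "Guangdong",
    "Guangxi", "Hainan", "Chongqing", "Sichuan", "Guizhou", "Yunnan",
    "Tibet", "Shaanxi", "Gansu", "Qinghai", "Ningxia", "Xinjiang")
}

#' Queen-contiguity adjacency for mainland China
#'
#' First-order queen contiguity among the 31 province-level units, with a
#' Hainan-Guangdong bridge so that no region is an island. This is one
#' conventional choice of neighbourhood structure among several; analyses
#' sensitive to the weight matrix should be repeated under alternatives.
#'
#' @return An `adjacency_map` (see [read_adjacency()]).
#' @export
china_adjacency <- function() {
  path <- system.file("extdata", "china_adjacency.txt",
                      package = "couplecoord", mustWork = TRUE)
  read_adjacency(path, regions = china_regions())
}
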