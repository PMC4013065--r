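#' Relative rosette area growth rate
#'
#' The classical relative growth rate between consecutive imaging dates:
#' `(ln A(t2) - ln A(t1)) / (t2 - t1)`, in units of 1/day, reported at the
#' interval midpoint `(t1 + t2) / 2`. Exponential growth
#' `A(t) = A0 * exp(k t)` therefore returns exactly `k` on every interval,
#' and the statistic is invariant to rescaling all areas by a constant.
#'
#' @param das numeric vector of observation times in days after
#'   stratification, strictly increasing.
#' @param area rosette areas (mm^2) at those times, all > 0.
#' @return a `data.frame` with columns `mid_das` and `rragr`, one row per
#'   consecutive interval (zero rows for a single time point).
#' @examples
#' rragr(c(17, 22), c(100, 200)) # log(2) / 5
#' @export
rragr <- function(das, area) {
  if (length(das) != length(area)) stop("`das` and `area` lengths differ")
  if (anyNA(das) || anyNA(area)) stop("missing values in growth series")
  if (any(diff(das) <= 0)) stop("`das` must be strictly increasing")
  if (any(area <= 0)) stop("non-positive rosette area in growth series")
  n <- length(das)
  if (n < 2L)
    return(data.frame(mid_das = numeric(0), rragr = numeric(0)))
  dt <- diff(das)
  data.frame(mid_das = (das[-n] + das[-1]) / 2,
             rragr = diff(log(area)) / dt)
}

#' Growth rates for every plant in a descriptor table
#'
#' Applies [rragr()] per `plant_id` over available consecutive time points
#' (no interpolation across missing dates).
#'
#' @param table a descriptor table (see [read_descriptor_table()]) with
#'   columns `plant_id`, `ecotype`, `das` and `area`.
#' @return a long `data.frame` with columns `plant_id`, `ecotype`,
#'   `mid_das`, `rragr`.
#' @export
rragr_table <- function(table) {
  need <- c("plant_id", "ecotype", "das", "area")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  parts <- split(table, table$plant_id)
  out <- lapply(parts, function(d) {
    d <- d[order(d$das), ]
    g <- rragr(d$das, d$area)
    if (nrow(g) == 0L) return(NULL)
    data.frame(plant_id = d$plant_id[1], ecotype = d$ecotype[1], g)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (is.null(res))
    res <- data.frame(plant_id = character(0), ecotype = character(0),
                      mid_das = numeric(0), rragr = numeric(0))
  res
}
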