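# Log transforms and the independent cortical-folding components K, I, S.

# Coefficient vectors over (x, y, z) = (log10 A_t, log10 T^2, log10 A_e).
# Rows are mutually orthogonal; K and S are invariant under isometric
# rescaling (A_t, A_e ~ lambda^2, T ~ lambda), I shifts by 3*log10(lambda^2).
KIS_COEF <- rbind(K = c(1,    1 / 4, -5 / 4),
                  I = c(1,    1,      1),
                  S = c(3 / 2, -9 / 4, 3 / 4))

#' Log-transform a morphometry table
#'
#' Replaces every value by its base-10 logarithm, so metrics of different
#' dimensionality (thickness vs. area vs. volume) can be modelled on a
#' common scale, and suffixes metric names with \code{"_log10"} to record
#' the transform. K, I and S are already logarithmic quantities and are
#' passed through unchanged.
#'
#' @param tab Tidy morphometry \code{data.frame}; all values of
#'   non-logarithmic metrics must be strictly positive.
#' @return The table with transformed values and renamed metrics.
#' @export
log_metrics <- function(tab) {
  validate_morphometry(tab)
  to_log <- !(tab$metric %in% c("K", "I", "S")) &
    !grepl("_log10$", tab$metric)
  bad <- to_log & tab$value <= 0
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("non-positive value for subject '", tab$subject_id[i],
         "', region '", tab$region[i], "', metric '", tab$metric[i], "'")
  }
  tab$value[to_log] <- log10(tab$value[to_log])
  tab$metric[to_log] <- paste0(tab$metric[to_log], "_log10")
  tab
}

#' Independent folding components K, I, S
#'
#' Derives the three orthogonal components of the universal cortical
#' folding scaling law from hemisphere-level total pial surface area,
#' exposed (smoothed) surface area, and average cortical thickness.
#' With \eqn{x = \log_{10} A_t}, \eqn{y = \log_{10} T^2},
#' \eqn{z = \log_{10} A_e}:
#' \deqn{K = x + y/4 - 5z/4,\quad I = x + y + z,\quad
#'       S = 3x/2 - 9y/4 + 3z/4.}
#' K reflects the tension/offset term of the scaling law, I the isometric
#' size, and S the remaining shape (folding complexity) information.
#' Isometric rescaling of the hemisphere changes I but leaves K and S
#' unchanged. Note T enters through its square inside the logarithm: the
#' input is plain average thickness in mm and the squaring is internal.
#'
#' @param A_t Total pial surface area, mm^2 (vectorised).
#' @param A_e Exposed surface area, mm^2.
#' @param T_avg Average cortical thickness, mm.
#' @return \code{data.frame} with columns \code{K}, \code{I}, \code{S}.
#' @export
compute_kis <- function(A_t, A_e, T_avg) {
  if (any(A_t <= 0) || any(A_e <= 0) || any(T_avg <= 0))
    stop("A_t, A_e, and T_avg must all be strictly positive")
  if (any(A_t < A_e))
    warning("total pial area smaller than exposed area for ",
            sum(A_t < A_e), " input(s); folded cortex expects A_t >= A_e")
  xyz <- cbind(log10(A_t), log10(T_avg^2), log10(A_e))
  out <- xyz %*% t(KIS_COEF)
  data.frame(K = out[, "K"], I = out[, "I"], S = out[, "S"])
}

#' Append K, I, S records to a cohort's morphometry
#'
#' Computes the folding components per subject and hemisphere from the
#' raw folding-toolbox metrics already present in the table
#' (\code{total_pial_area_mm2}, \code{exposed_area_mm2},
#' \code{avg_thickness_mm} at region \code{"hemisphere"}) and appends
#' them as metrics \code{K}, \code{I}, \code{S}.
#'
#' @param tab Tidy morphometry \code{data.frame} containing the three raw
#'   folding metrics.
#' @return The table with K/I/S rows appended.
#' @export
add_kis <- function(tab) {
  validate_morphometry(tab)
  fold <- tab[tab$region == "hemisphere" &
                tab$metric %in% c("total_pial_area_mm2", "exposed_area_mm2",
                                  "avg_thickness_mm"), ]
  if (!nrow(fold)) stop("no folding-toolbox metrics present")
  wide <- reshape(fold, idvar = c("subject_id", "hemisphere", "region"),
                  timevar = "metric", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  need <- c("total_pial_area_mm2", "exposed_area_mm2", "avg_thickness_mm")
  miss <- setdiff(need, names(wide))
  if (length(miss))
    stop("incomplete folding metrics; missing ", paste(miss, collapse = ", "))
  kis <- compute_kis(wide$total_pial_area_mm2, wide$exposed_area_mm2,
                     wide$avg_thickness_mm)
  new <- do.call(rbind, lapply(c("K", "I", "S"), function(m)
    data.frame(subject_id = wide$subject_id, hemisphere = wide$hemisphere,
               region = "hemisphere", metric = m, value = kis[[m]],
               stringsAsFactors = FALSE)))
  out <- rbind(tab, new)
  rownames(out) <- NULL
  validate_morphometry(out)
}
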