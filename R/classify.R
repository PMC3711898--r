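#' Classify the Crabtree phenotype from ethanol and biomass yields
#'
#' Assigns each strain to one of three phenotype categories from its
#' ethanol yield `Y_E/S` and biomass yield `Y_X/S` (both g per g
#' glucose):
#'
#' * `STRONG_POSITIVE` - over 5.5 g glucose per g biomass
#'   (`Y_X/S < 0.18`) and over 0.33 g ethanol per g glucose;
#' * `INTERMEDIATE` - 3-5 g glucose per g biomass
#'   (`0.18 <= Y_X/S <= 0.33`);
#' * `NEGATIVE_LIKE` - under 3 g glucose per g biomass
#'   (`Y_X/S > 0.33`) with almost no ethanol (`Y_E/S < 0.15`).
#'
#' The published bounds do not tile the whole yield plane (e.g. a strain
#' with `Y_X/S < 0.18` but `Y_E/S <= 0.33`); such cases are assigned to
#' the nearest category region in yield space and flagged
#' `outside_published_bounds`.
#'
#' @param data Data frame with the yield columns (one row per strain),
#'   or `NULL` to classify the bare vectors in `ethanol_yield` /
#'   `biomass_yield`.
#' @param ethanol_yield,biomass_yield Column names (tidy-eval) when
#'   `data` is supplied, otherwise numeric vectors.
#' @return The input with columns `crabtree_class` (factor:
#'   `STRONG_POSITIVE`, `INTERMEDIATE`, `NEGATIVE_LIKE`),
#'   `glucose_per_biomass` (g glucose per g biomass, `1 / Y_X/S`) and
#'   `class_flag` appended (a tibble is built when `data` is `NULL`).
#' @export
#' @examples
#' classify_crabtree(tibble::tibble(ethanol_yield = c(0.39, 0, 0.30),
#'                                  biomass_yield = c(0.16, 0.57, 0.23)))
classify_crabtree <- function(data = NULL, ethanol_yield = ethanol_yield,
                              biomass_yield = biomass_yield) {
  if (is.null(data)) {
    yes <- ethanol_yield
    yxs <- biomass_yield
    data <- tibble::tibble(ethanol_yield = yes, biomass_yield = yxs)
  } else {
    yes <- dplyr::pull(data, {{ ethanol_yield }})
    yxs <- dplyr::pull(data, {{ biomass_yield }})
  }
  if (any(!is.finite(yes)) || any(!is.finite(yxs))) {
    stop("yields must be finite")
  }
  if (any(yxs <= 0)) stop("biomass yield must be positive")
  cls <- character(length(yes))
  flag <- character(length(yes))
  for (i in seq_along(yes)) {
    res <- classify_one(yes[i], yxs[i])
    cls[i] <- res$class
    flag[i] <- res$flag
  }
  data %>%
    dplyr::mutate(
      crabtree_class = factor(cls, levels = c("STRONG_POSITIVE",
                                              "INTERMEDIATE",
                                              "NEGATIVE_LIKE")),
      glucose_per_biomass = 1 / yxs,
      class_flag = flag
    )
}

classify_one <- function(yes, yxs) {
  if (yxs < 0.18 && yes > 0.33) {
    return(list(class = "STRONG_POSITIVE", flag = ""))
  }
  if (yxs > 0.33 && yes < 0.15) {
    return(list(class = "NEGATIVE_LIKE", flag = ""))
  }
  if (yxs >= 0.18 && yxs <= 0.33) {
    return(list(class = "INTERMEDIATE", flag = ""))
  }
  # outside the published bounds: nearest category region in yield space
  d_strong <- dist_to_box(yes, yxs, c(0.33, ETHANOL_YIELD_MAX), c(0, 0.18))
  d_inter <- dist_to_box(yes, yxs, c(0, ETHANOL_YIELD_MAX), c(0.18, 0.33))
  d_neg <- dist_to_box(yes, yxs, c(0, 0.15), c(0.33, Inf))
  d <- c(STRONG_POSITIVE = d_strong, INTERMEDIATE = d_inter,
         NEGATIVE_LIKE = d_neg)
  # ties (boundary cases) resolve toward the middle category
  ord <- c("INTERMEDIATE", "STRONG_POSITIVE", "NEGATIVE_LIKE")
  winner <- ord[which.min(d[ord])]
  list(class = winner, flag = "outside_published_bounds")
}

dist_to_box <- function(x, y, xr, yr) {
  dx <- max(xr[1] - x, 0, x - xr[2])
  dy <- max(yr[1] - y, 0, y - yr[2])
  sqrt(dx^2 + dy^2)
}
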