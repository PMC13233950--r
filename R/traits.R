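## Derived sex-bias variables and composite indices.
##
## Conventions: demographic biases are log(female/male) ratios (positive =
## female value larger); size dimorphism is log(male/female) mass; composite
## indices are means of z-scored components over the species entering the
## analysis.

#' Log-ratio sex bias
#'
#' `log(female/male)`; zero when the sexes are equal, positive when the
#' female value is larger. Used for juvenile mortality, adult mortality and
#' age-at-maturation biases. Missing values propagate.
#'
#' @param female,male Positive numeric vectors (rates, ages...).
#' @return Numeric vector of log ratios.
#' @export
log_ratio_bias <- function(female, male) {
  bad <- (!is.na(female) & female <= 0) | (!is.na(male) & male <= 0)
  if (any(bad)) stop("log_ratio_bias requires strictly positive inputs")
  log(female / male)
}

#' Sexual size dimorphism
#'
#' `log(male mass / female mass)` — note the male-over-female orientation,
#' opposite to the demographic biases.
#'
#' @param mass_m,mass_f Positive numeric vectors (grams).
#' @return Numeric vector.
#' @export
size_dimorphism <- function(mass_m, mass_f) {
  bad <- (!is.na(mass_m) & mass_m <= 0) | (!is.na(mass_f) & mass_f <= 0)
  if (any(bad)) stop("size_dimorphism requires strictly positive masses")
  log(mass_m / mass_f)
}

#' Social mating-system bias
#'
#' Difference between male and female polygamy scores (each on the 0-4
#' incidence scale). Positive values lean polygynous with the default
#' `orientation = "male_minus_female"`.
#'
#' @param polyg_m,polyg_f Integer scores in 0..4.
#' @param orientation `"male_minus_female"` (default) or
#'   `"female_minus_male"`.
#' @return Integer vector.
#' @export
mating_system_bias <- function(polyg_m, polyg_f,
                               orientation = c("male_minus_female", "female_minus_male")) {
  orientation <- match.arg(orientation)
  chk <- function(x, nm) {
    xx <- x[!is.na(x)]
    if (length(xx) && (any(xx < 0 | xx > 4) || any(xx != round(xx))))
      stop(nm, " scores must be integers in 0..4")
  }
  chk(polyg_m, "male polygamy"); chk(polyg_f, "female polygamy")
  d <- polyg_m - polyg_f
  if (orientation == "female_minus_male") d <- -d
  d
}

## Internal: PCA on the correlation matrix with varimax rotation.
## Loadings are rotated orthonormal eigenvectors; scores are standardized
## data projected on them. Sign of each component oriented so its mean
## loading is positive.
pca_varimax <- function(M, ncomp = 1L) {
  M <- as.matrix(M)
  keep <- complete.cases(M)
  if (sum(keep) < 2) stop("need at least 2 complete rows for PCA")
  sds <- apply(M[keep, , drop = FALSE], 2, sd)
  if (any(sds == 0)) stop("constant column(s): ", paste(colnames(M)[sds == 0], collapse = ", "))
  Z <- scale(M[keep, , drop = FALSE])
  p <- prcomp(Z, center = FALSE, scale. = FALSE)
  ev <- p$sdev^2
  L <- p$rotation[, seq_len(ncomp), drop = FALSE]
  if (ncomp >= 2) {
    ## rotate variance-scaled loadings (the varimax criterion is computed on
    ## these, as is conventional), then apply the same rotation to the
    ## orthonormal axes
    A <- L %*% diag(p$sdev[seq_len(ncomp)], ncomp)
    R <- varimax(A, normalize = FALSE)$rotmat
    L <- L %*% R
    expl <- colSums((A %*% R)^2) / sum(ev)
  } else {
    expl <- ev[seq_len(ncomp)] / sum(ev)
  }
  sgn <- ifelse(colMeans(L) >= 0, 1, -1)
  L <- sweep(L, 2, sgn, `*`)
  scores_part <- Z %*% L
  scores <- matrix(NA_real_, nrow(M), ncomp,
                   dimnames = list(rownames(M), paste0("PC", seq_len(ncomp))))
  scores[keep, ] <- scores_part
  structure(list(loadings = L, scores = scores,
                 explained_variance = unname(expl),
                 rotation = "varimax", n_used = sum(keep)),
            class = "pca_result")
}

#' Plumage dimorphism index (rotated PC1 of five body-region scores)
#'
#' Principal component analysis (correlation matrix) of the five
#' body-region plumage dimorphism scores (head, back, belly, wings, tail;
#' each -2..2, positive = male brighter), with varimax rotation when more
#' than one component is retained. The first component, sign-oriented so
#' higher = more male-biased brightness, is the plumage dimorphism index.
#'
#' @param plumage_scores Species x 5 matrix/data frame of integer scores.
#' @param ncomp Number of components to retain (default 1).
#' @return A `pca_result`: `loadings`, `scores`, `explained_variance`,
#'   `rotation`.
#' @export
plumage_pc1 <- function(plumage_scores, ncomp = 1L) {
  M <- as.matrix(plumage_scores)
  xx <- M[!is.na(M)]
  if (any(xx < -2 | xx > 2)) stop("plumage scores must lie in -2..2")
  pca_varimax(M, ncomp = ncomp)
}

#' Female parental-care index (PC1 of brooding and chick attendance)
#'
#' Chick attendance is the development-mode-specific combination used in the
#' care scoring: chick feeding for altricial / semi-altricial /
#' semi-precocial species and chick defence for precocial species. PC1 of
#' female brooding and chick-attendance participation (0-4 scales) is the
#' female-care index, oriented so higher = more female care.
#'
#' @param care_brood Female brooding participation (0-4).
#' @param care_feed Female chick-feeding participation (0-4).
#' @param care_defence Female chick-defence participation (0-4).
#' @param development_mode Character vector: `"precocial"`,
#'   `"semi-precocial"`, `"semi-altricial"` or `"altricial"`.
#' @return A `pca_result` whose `scores[, 1]` is the care index; the
#'   attendance column used per species is in `attr(, "attendance")`.
#' @export
care_pc1 <- function(care_brood, care_feed, care_defence, development_mode) {
  mode <- match.arg(development_mode,
                    c("precocial", "semi-precocial", "semi-altricial", "altricial"),
                    several.ok = TRUE)
  attend <- ifelse(development_mode == "precocial", care_defence, care_feed)
  M <- cbind(brood = care_brood, attend = attend)
  xx <- M[!is.na(M)]
  if (any(xx < 0 | xx > 4)) stop("care scores must lie in 0..4")
  out <- pca_varimax(M, ncomp = 1L)
  attr(out, "attendance") <- attend
  out
}

#' Residual testes mass
#'
#' OLS residuals of log10 testes mass on log10 male body mass, the standard
#' allometry correction for relative investment in sperm competition.
#'
#' @param testes_mass,mass_m Positive numeric vectors (grams).
#' @return Numeric vector of residuals (NA where either input is missing).
#' @export
testes_residual <- function(testes_mass, mass_m) {
  ok <- !is.na(testes_mass) & !is.na(mass_m)
  if (any(testes_mass[ok] <= 0) || any(mass_m[ok] <= 0))
    stop("testes and body masses must be strictly positive")
  if (sum(ok) < 3) stop("need at least 3 species with both testes and body mass")
  lt <- log10(testes_mass); lm_ <- log10(mass_m)
  fit <- lm(lt ~ lm_, subset = ok)
  out <- rep(NA_real_, length(testes_mass))
  out[ok] <- resid(fit)
  out
}

#' Composite bias index (mean of z-scored components)
#'
#' Standardises each component (sample mean/SD over the species entering the
#' analysis) and averages. The demography composite averages juvenile
#' mortality, maturation and adult mortality biases; the pre-copulatory
#' composite averages size dimorphism, plumage dimorphism and mating-system
#' bias; the post-copulatory composite averages residual testes mass and
#' extra-pair paternity.
#'
#' @param components Named list (or data frame) of numeric vectors of equal
#'   length.
#' @param require_complete If `TRUE` (default) species missing any component
#'   get `NA`; otherwise the mean of the available components is used when at
#'   least `min_components` are present.
#' @param min_components Minimum components per species when
#'   `require_complete = FALSE`.
#' @return Numeric vector (z-score scale, mean approximately 0).
#' @export
composite_index <- function(components, require_complete = TRUE, min_components = 2L) {
  M <- do.call(cbind, lapply(components, as.numeric))
  colnames(M) <- names(components)
  zs <- apply(M, 2, function(x) {
    s <- sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) return(rep(NA_real_, length(x)))
    (x - mean(x, na.rm = TRUE)) / s
  })
  bad <- colnames(M)[apply(M, 2, function(x) {
    s <- sd(x, na.rm = TRUE); is.na(s) || s == 0
  })]
  if (length(bad)) stop("zero-variance component(s): ", paste(bad, collapse = ", "))
  if (require_complete) {
    out <- rowMeans(zs)
  } else {
    k <- rowSums(!is.na(zs))
    out <- rowMeans(zs, na.rm = TRUE)
    out[k < min_components] <- NA_real_
  }
  out
}

#' Merge birth sex ratio sources with fledging priority
#'
#' Fledging sex ratios account for sex-specific nestling mortality and are
#' the primary source; hatching ratios fill gaps. A provenance column
#' records which source supplied each species.
#'
#' @param fledging_sr,hatching_sr Numeric vectors of proportions of males.
#' @return Data frame with columns `bsr` and `bsr_source`.
#' @export
merge_bsr <- function(fledging_sr, hatching_sr) {
  bsr <- ifelse(!is.na(fledging_sr), fledging_sr, hatching_sr)
  src <- ifelse(!is.na(fledging_sr), "fledging",
                ifelse(!is.na(hatching_sr), "hatching", NA_character_))
  data.frame(bsr = bsr, bsr_source = src, stringsAsFactors = FALSE)
}

#' Build the full derived-variable table from raw species records
#'
#' Applies every construction: log-ratio demographic biases, size
#' dimorphism, plumage PC1, mating-system bias, care PC1, residual testes
#' mass, and the three composite indices.
#'
#' @param records Data frame of raw species records (see the column
#'   dictionary in the package vignette); must contain a `species` column.
#' @param require_complete Passed to [composite_index()].
#' @return Data frame of derived variables keyed by `species`, with an
#'   attribute `"provenance"` listing the components entering each composite.
#' @export
build_derived_table <- function(records, require_complete = TRUE) {
  stopifnot("species" %in% names(records))
  r <- records
  out <- data.frame(species = r$species, stringsAsFactors = FALSE)
  out$asr <- r$asr
  out$juv_mort_bias <- log_ratio_bias(r$juv_mort_f, r$juv_mort_m)
  out$ad_mort_bias <- log_ratio_bias(r$ad_mort_f, r$ad_mort_m)
  out$mat_bias <- log_ratio_bias(r$mat_f, r$mat_m)
  out$ssd <- size_dimorphism(r$mass_m, r$mass_f)
  plum_cols <- c("plum_head", "plum_back", "plum_belly", "plum_wings", "plum_tail")
  out$plumage_pc1 <- plumage_pc1(r[, plum_cols])$scores[, 1]
  out$mating_bias <- mating_system_bias(r$polyg_m, r$polyg_f)
  out$care_pc1 <- care_pc1(r$care_brood, r$care_feed, r$care_defence,
                           r$development_mode)$scores[, 1]
  has_postcop <- all(c("testes_mass", "epp") %in% names(r))
  if (has_postcop) {
    out$testes_resid <- testes_residual(r$testes_mass, r$mass_m)
    out$epp <- r$epp
  }
  prov <- list(
    demography_bias = c("juv_mort_bias", "mat_bias", "ad_mort_bias"),
    precop_bias = c("ssd", "plumage_pc1", "mating_bias"))
  if (has_postcop) prov$postcop_bias <- c("testes_resid", "epp")
  out$demography_bias <- composite_index(out[prov$demography_bias], require_complete)
  out$precop_bias <- composite_index(out[prov$precop_bias], require_complete)
  if (has_postcop)
    out$postcop_bias <- composite_index(out[prov$postcop_bias], require_complete)
  attr(out, "provenance") <- prov
  out
}
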