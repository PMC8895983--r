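#' Trait architecture specification
#'
#' Describes the genetic architecture used by [simulate_traits]: QTL with
#' family-nested additive effects (possibly shared across traits, i.e.
#' pleiotropic), per-trait line-mean heritability targets, and optional
#' segregation distortion.
#'
#' @param effects long data frame with columns `marker`, `trait`,
#'   `family`, `effect`. `effect` is the difference between the two
#'   genotype-class means (0/1 parental-origin coding) in that family, in
#'   trait units.
#' @param h2 named numeric vector of target line-mean heritabilities in
#'   (0, 1], one per trait.
#' @param distortion optional data frame `marker`, `family`, `freq` used
#'   when simulating the population (see [simulate_family]).
#' @return A `trait_architecture` object.
#' @export
trait_architecture <- function(effects, h2, distortion = NULL) {
  if (nrow(effects) > 0)
    stopifnot(all(c("marker", "trait", "family", "effect") %in% names(effects)))
  if (any(h2 <= 0 | h2 > 1)) stop("h2 targets must lie in (0, 1]")
  traits <- union(names(h2), unique(effects$trait))
  if (!all(traits %in% names(h2)))
    stop("every trait with effects needs an h2 target")
  structure(list(effects = effects, h2 = h2, distortion = distortion),
            class = "trait_architecture")
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat("Trait architecture:", length(x$h2), "trait(s),",
      length(unique(x$effects$marker)), "QTL\n")
  invisible(x)
}

#' Build correlated family-nested QTL effects for several traits
#'
#' Draws per-family allelic effects for one QTL affecting `traits`, with
#' cross-trait correlation `rho` between the family effect vectors (the
#' operational meaning of pleiotropy at a shared QTL: families in which
#' the allele raises trait A also tend to raise -- or, for negative rho,
#' lower -- trait B).
#'
#' @param marker marker id of the QTL.
#' @param traits character vector of affected traits.
#' @param families character vector of family ids.
#' @param mean_effect numeric mean effect per trait (recycled).
#' @param sd_effect numeric between-family effect SD per trait (recycled).
#' @param rho common cross-trait correlation of family effects.
#' @param seed integer seed.
#' @return long effects data frame suitable for [trait_architecture].
#' @export
pleiotropic_qtl <- function(marker, traits, families, mean_effect = 1,
                            sd_effect = 0.3, rho = 0.8, seed = 1) {
  k <- length(traits)
  mean_effect <- rep_len(mean_effect, k)
  sd_effect <- rep_len(sd_effect, k)
  C <- matrix(rho, k, k); diag(C) <- 1
  L <- chol(C)
  set.seed(seed)
  Z <- matrix(stats::rnorm(length(families) * k), ncol = k) %*% L
  eff <- sweep(sweep(Z, 2, sd_effect, "*"), 2, mean_effect, "+")
  data.frame(marker = marker,
             trait = rep(traits, each = length(families)),
             family = rep(families, k),
             effect = as.vector(eff),
             stringsAsFactors = FALSE)
}

#' Write / read a trait architecture as YAML
#' @param arch a [trait_architecture].
#' @param path file path.
#' @export
write_architecture <- function(arch, path) {
  yaml::write_yaml(precision = 15,
                   list(h2 = as.list(arch$h2),
                        effects = lapply(seq_len(nrow(arch$effects)), function(i)
                          as.list(arch$effects[i, ])),
                        distortion = if (is.null(arch$distortion)) NULL else
                          lapply(seq_len(nrow(arch$distortion)), function(i)
                            as.list(arch$distortion[i, ]))),
                   path)
  invisible(path)
}

#' @rdname write_architecture
#' @export
read_architecture <- function(path) {
  y <- yaml::read_yaml(path)
  eff <- do.call(rbind, lapply(y$effects, as.data.frame))
  dis <- if (is.null(y$distortion)) NULL else
    do.call(rbind, lapply(y$distortion, as.data.frame))
  trait_architecture(eff, unlist(y$h2), dis)
}
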