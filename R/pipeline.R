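#' Fusion configuration
#'
#' Bundles the tunable parameters of the fusion pipeline. The defaults —
#' alpha 4 and 3 decomposition scales — are the setting the method performs
#' best at; directions double with scale.
#'
#' @param alpha Nonnegative modulation parameter of the low-frequency
#'   structural-information rule (default 4). 0 degrades the rule to a
#'   plain average.
#' @param scales Number of shearlet decomposition scales (default 3).
#' @param directions Integer vector, directional bands per scale, coarse to
#'   fine (default `c(4, 8, 16)`).
#' @param pcaScope `"band"` (default) computes PCA weights independently
#'   for every (scale, direction) high-frequency band pair; `"global"`
#'   pools the coefficients of all high-frequency bands into one weight
#'   pair.
#' @param normalize Scale integer input images to [0, 1] on read (default
#'   TRUE; kept as a switch for callers feeding pre-normalized floats).
#' @return A list of class `FusionConfig`.
#' @examples
#' fusionConfig()
#' @export
fusionConfig <- function(alpha = 4, scales = 3L,
                         directions = c(4L, 8L, 16L),
                         pcaScope = c("band", "global"),
                         normalize = TRUE) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0)
    stopConfig("alpha must be a nonnegative scalar")
  scales <- as.integer(scales)
  directions <- as.integer(directions)
  if (scales < 1L) stopConfig("scales must be >= 1")
  if (length(directions) != scales)
    stopConfig("directions must have one entry per scale")
  if (any(directions < 2L) || any(directions %% 2L != 0L))
    stopConfig("each direction count must be even and >= 2")
  pcaScope <- match.arg(pcaScope)
  structure(list(alpha = alpha, scales = scales, directions = directions,
                 pcaScope = pcaScope, normalize = isTRUE(normalize)),
            class = "FusionConfig")
}

#' @export
print.FusionConfig <- function(x, ...) {
  cat(sprintf("FusionConfig: alpha = %g, scales = %d, directions [%s], PCA %s\n",
              x$alpha, x$scales, paste(x$directions, collapse = ", "),
              x$pcaScope))
  invisible(x)
}

#' Fuse a functional/structural image pair
#'
#' Runs the whole pipeline on a registered pair: (1) the functional color
#' image is converted to intensity plus chroma by the linear IHS transform;
#' (2) its intensity plane and the structural image are each decomposed
#' with the non-subsampled shearlet transform; (3) the two low-frequency
#' sub-bands are fused by the structural-information rule with
#' `config$alpha`; (4) every matching directional high-frequency band pair
#' is fused by PCA eigenweights; (5) the fused sub-bands are reconstructed
#' into a fused intensity plane; (6) that plane is substituted into the IHS
#' triple and mapped back to RGB with the original chroma planes. The
#' result is deterministic and is not clipped — use
#' [fusedImage()]/[writeOutputImage()] for display values.
#'
#' @param functional H x W x 3 numeric array (pseudo-color functional
#'   image) in [0, 1]; an H x W matrix is replicated to three channels.
#' @param structural H x W numeric matrix (grayscale structural image) in
#'   [0, 1].
#' @param config A [fusionConfig()] list.
#' @return A [FusionResult-class]; its log records the intensity densities,
#'   alpha, and the per-band PCA weights, so any run can be audited against
#'   the fusion rules by hand.
#' @examples
#' p <- grayscaleTwinPair(size = 64, seed = 1)
#' res <- fusePair(p$functional, p$structural,
#'                 fusionConfig(scales = 2, directions = c(4, 8)))
#' max(abs(fusedImage(res) - p$functional))   # ~1e-15: degenerate idempotence
#' @export
fusePair <- function(functional, structural, config = fusionConfig()) {
  if (!inherits(config, "FusionConfig"))
    stopConfig("config must come from fusionConfig()")
  if (is.matrix(functional))
    functional <- array(rep(functional, 3L), dim = c(dim(functional), 3L))
  if (length(dim(functional)) != 3L || dim(functional)[3] != 3L)
    stopShape("functional image must be H x W x 3")
  if (!is.matrix(structural))
    stopShape("structural image must be a single-channel matrix")
  if (!identical(dim(functional)[1:2], dim(structural)))
    stopShape("images are not registered: functional is ",
              paste(dim(functional)[1:2], collapse = " x "),
              " but structural is ",
              paste(dim(structural), collapse = " x "),
              "; register the pair to a common grid first")
  checkFinite(functional, "functional image")
  checkFinite(structural, "structural image")

  trip <- rgbToIHS(functional)
  bank <- shearletFilterBank(nrow(structural), ncol(structural),
                             scales = config$scales,
                             directions = config$directions)
  decF <- nsstDecompose(trip@intensity, bank)
  decS <- nsstDecompose(structural, bank)

  idF <- intensityDensity(decF@lfs)
  idS <- intensityDensity(decS@lfs)
  fusedLfs <- fuseLowpassSI(decF@lfs, decS@lfs, alpha = config$alpha)

  globalW <- NULL
  if (config$pcaScope == "global") {
    allF <- unlist(lapply(decF@hfs, function(s) lapply(s, as.vector)))
    allS <- unlist(lapply(decS@hfs, function(s) lapply(s, as.vector)))
    globalW <- pcaWeights(as.matrix(allF), as.matrix(allS))
  }

  fusedHfs <- vector("list", config$scales)
  wlog <- list()
  for (j in seq_len(config$scales)) {
    k <- config$directions[j]
    fusedHfs[[j]] <- vector("list", k)
    for (i in seq_len(k)) {
      w <- if (is.null(globalW))
        pcaWeights(decF@hfs[[j]][[i]], decS@hfs[[j]][[i]]) else globalW
      fusedHfs[[j]][[i]] <- fuseHighpassPCA(decF@hfs[[j]][[i]],
                                            decS@hfs[[j]][[i]], w)
      wlog[[length(wlog) + 1L]] <-
        data.frame(scale = j, direction = i,
                   wFunctional = w@weights[1L], wStructural = w@weights[2L])
    }
  }

  fusedDec <- new("ShearletDecomposition", lfs = fusedLfs, hfs = fusedHfs,
                  directions = config$directions, dims = bank@dims)
  fusedI <- nsstReconstruct(fusedDec)
  fused <- ihsToRGB(substituteIntensity(trip, fusedI))

  new("FusionResult", fused = fused, config = unclass(config),
      log = list(idFunctional = idF, idStructural = idS,
                 alpha = config$alpha,
                 pcaWeights = do.call(rbind, wlog)))
}
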