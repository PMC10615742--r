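#' Default lipid-class composition and acyl-chain pool
#'
#' `defaultLipidClassCounts()` allocates `nLipids` lipids over 26 lipid
#' classes in proportions typical of a targeted brain lipidomics panel
#' (glycerophospholipids dominating, with sphingolipids, glycerolipids and
#' lyso-species), using largest-remainder rounding so the counts sum
#' exactly to `nLipids`. `defaultAcylChainPool()` returns 29 "C:D" fatty
#' acyl chains with sampling weights favouring the abundant brain chains
#' (16:0, 18:0, 18:1, 20:4, 22:6).
#'
#' @param nLipids Total number of lipids to allocate.
#' @return A named integer vector of class counts / a named numeric vector
#'   of chain weights.
#' @export
defaultLipidClassCounts <- function(nLipids = 464) {
  base <- c(PC = 90, PE = 70, `PE(P)` = 30, `PE(O)` = 20, PS = 35, PI = 25,
            PG = 12, PA = 10, LPC = 12, LPE = 8, LPS = 4, LPI = 4, LPG = 3,
            LPA = 3, SM = 30, Cer = 25, HexCer = 15, LacCer = 6, Sph = 4,
            DG = 20, TG = 45, CE = 8, FA = 15, CL = 12, BMP = 6, MG = 2)
  raw <- base / sum(base) * nLipids
  cnt <- floor(raw)
  rem <- nLipids - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1
  }
  stats::setNames(as.integer(cnt), names(base))
}

#' @rdname defaultLipidClassCounts
#' @export
defaultAcylChainPool <- function() {
  c(`12:0` = 0.2, `14:0` = 0.6, `15:0` = 0.2, `16:0` = 4, `16:1` = 1,
    `17:0` = 0.3, `17:1` = 0.2, `18:0` = 4, `18:1` = 4, `18:2` = 2,
    `18:3` = 0.5, `19:0` = 0.2, `20:0` = 0.4, `20:1` = 1, `20:2` = 0.5,
    `20:3` = 0.8, `20:4` = 3, `20:5` = 0.8, `21:0` = 0.1, `22:0` = 0.4,
    `22:1` = 0.3, `22:4` = 0.8, `22:5` = 0.8, `22:6` = 3, `23:0` = 0.1,
    `24:0` = 0.6, `24:1` = 0.8, `24:2` = 0.3, `26:0` = 0.2)
}

## chains carried by one lipid of a given class
.chainsPerClass <- function(cls) {
  if (cls %in% c("LPC", "LPE", "LPS", "LPI", "LPG", "LPA", "MG", "Sph",
                 "CE", "FA")) 1L
  else if (cls == "TG") 3L
  else if (cls == "CL") 4L
  else 2L
}

#' Simulate a lipidomics table with known group effects
#'
#' Generates log-normally distributed abundances for `nLipids` lipids over
#' two sample groups, with class and acyl-chain annotations drawn from the
#' default (or supplied) pools. Effects are specified as standardized mean
#' differences: each targeted lipid's log2 abundance is shifted between
#' groups by `d * sigma`, so the injected Cohen's d is known exactly.
#' Targets may be a lipid class (`"class:PC"`), a fatty acid
#' (`"fa:20:1"`, matching any lipid carrying that chain) or an explicit
#' vector of lipid ids.
#'
#' @param nLipids Number of lipids (default 464).
#' @param classCounts Named class composition summing to `nLipids`.
#' @param acylPool Named chain weights (29 chains by default).
#' @param groupSizes Two group sizes, default `c(8, 8)`.
#' @param groupLabels Labels for the grouping factor.
#' @param factorName Name of the grouping factor in `colData`.
#' @param sigma Within-group SD of log2 abundance.
#' @param baseRange Range of per-lipid baseline log2 abundances.
#' @param effects List of `list(target =, d =, direction =)` entries;
#'   `direction = 1` means higher in the second group.
#' @param seed Optional integer seed.
#' @return A list with `table` (a [LipidTable-class]) and `truth` (a data
#'   frame with one row per effect lipid: `lipid_id`, `d`, `direction`).
#' @export
simulateLipidomics <- function(nLipids = 464, classCounts = NULL,
                               acylPool = defaultAcylChainPool(),
                               groupSizes = c(8, 8),
                               groupLabels = c("WT", "MUT"),
                               factorName = "genotype", sigma = 0.5,
                               baseRange = c(4, 14), effects = list(),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(classCounts)) classCounts <- defaultLipidClassCounts(nLipids)
  if (sum(classCounts) != nLipids)
    stop("class composition must sum to nLipids")
  cls <- rep(names(classCounts), classCounts)
  chains <- vapply(cls, function(k) {
    paste(sort(sample(names(acylPool), .chainsPerClass(k), replace = TRUE,
                      prob = acylPool)), collapse = ";")
  }, "")
  ids <- make.unique(paste0(cls, " ", gsub(";", "_", chains)), sep = "-")
  n1 <- groupSizes[1]; n2 <- groupSizes[2]
  grp <- factor(rep(groupLabels, c(n1, n2)), levels = groupLabels)
  mu <- runif(nLipids, baseRange[1], baseRange[2])

  shift <- numeric(nLipids)
  dAssigned <- numeric(nLipids)
  for (ef in effects) {
    target <- ef$target
    dir <- ef$direction %||% 1
    idx <- if (length(target) == 1L && grepl("^class:", target)) {
      which(cls == sub("^class:", "", target))
    } else if (length(target) == 1L && grepl("^fa:", target)) {
      fa <- sub("^fa:", "", target)
      which(vapply(strsplit(chains, ";"), function(ch) fa %in% ch, TRUE))
    } else {
      match(target, ids)
    }
    if (length(idx) == 0L || any(is.na(idx)))
      stop("effect target not present in the simulated composition: ",
           paste(target, collapse = ", "))
    shift[idx] <- dir * ef$d * sigma
    dAssigned[idx] <- ef$d
  }
  m <- matrix(rnorm(nLipids * (n1 + n2), sd = sigma), nrow = nLipids)
  m <- m + mu
  isG2 <- as.integer(grp) == 2L
  m[, isG2] <- m[, isG2] + shift / 2
  m[, !isG2] <- m[, !isG2] - shift / 2
  ab <- 2^m
  dimnames(ab) <- list(ids, sprintf("S%02d", seq_len(n1 + n2)))
  sampleData <- data.frame(grp, sex = "M", diet = "chow",
                           stringsAsFactors = FALSE)
  names(sampleData)[1] <- factorName
  tab <- LipidTable(ab, lipidClass = cls, acylChains = chains,
                    sampleData = sampleData)
  truth <- data.frame(lipid_id = ids[shift != 0 | dAssigned != 0],
                      d = dAssigned[shift != 0 | dAssigned != 0],
                      direction = sign(shift[shift != 0 | dAssigned != 0]),
                      stringsAsFactors = FALSE)
  list(table = tab, truth = truth)
}
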