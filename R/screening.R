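#' Total compound count of a hierarchical library
#'
#' Libraries are laid out as meta-tranche / tranche / collection levels
#' with a fixed number of compounds per collection, so the total is the
#' product of the four level counts.  The benchmark-scale layout
#' (10, 1000, 1000, 144) holds 1.44e9 compounds.
#'
#' @param h a \code{\link{library_hierarchy}} or list with the four counts.
#' @return numeric compound count.
#' @export
library_size <- function(h) {
  with(h, as.numeric(n_meta_tranches) * n_tranches_per_meta *
         n_collections_per_tranche * n_compounds_per_collection)
}

#' Hierarchy descriptor
#' @param n_meta_tranches,n_tranches_per_meta,n_collections_per_tranche,n_compounds_per_collection
#'   positive level counts.
#' @return object of class \code{library_hierarchy}.
#' @export
library_hierarchy <- function(n_meta_tranches, n_tranches_per_meta,
                              n_collections_per_tranche,
                              n_compounds_per_collection) {
  h <- list(n_meta_tranches = n_meta_tranches,
            n_tranches_per_meta = n_tranches_per_meta,
            n_collections_per_tranche = n_collections_per_tranche,
            n_compounds_per_collection = n_compounds_per_collection)
  stopifnot(all(unlist(h) >= 1))
  structure(h, class = "library_hierarchy")
}

#' Enumerate every compound of an on-disk library
#'
#' Walks the meta-tranche/tranche/collection tree in lexicographic order
#' and reads every ligand file, converting PDBQT to MOL2 molecules on the
#' fly (bond perception + Tripos typing) when \code{format = "PDBQT"}.
#' Collections may be plain directories or \code{.tar} archives of ligand
#' files.  Unreadable ligands are skipped and reported, never fatal.
#'
#' @param root library root directory.
#' @param format \code{"MOL2"} or \code{"PDBQT"}.
#' @return list with \code{molecules} (named list of \code{molecule}),
#'   \code{ids} (in traversal order) and \code{skipped} (data.frame of
#'   ligand id + error message).
#' @export
iterate_library <- function(root, format = c("MOL2", "PDBQT")) {
  format <- match.arg(format)
  ext <- if (format == "MOL2") "mol2" else "pdbqt"
  mols <- list()
  skipped <- list()
  metas <- sort(list.dirs(root, recursive = FALSE))
  for (meta in metas) {
    for (tranche in sort(list.dirs(meta, recursive = FALSE))) {
      colls <- sort(c(list.dirs(tranche, recursive = FALSE),
                      list.files(tranche, pattern = "\\.tar$",
                                 full.names = TRUE)))
      for (coll in colls) {
        cdir <- coll
        if (grepl("\\.tar$", coll)) {
          cdir <- tempfile("coll")
          dir.create(cdir)
          utils::untar(coll, exdir = cdir)
        }
        files <- sort(list.files(cdir, pattern = paste0("\\.", ext, "$"),
                                 full.names = TRUE, recursive = TRUE))
        for (fp in files) {
          id <- paste(basename(meta), basename(tranche),
                      sub("\\.tar$", "", basename(coll)),
                      tools::file_path_sans_ext(basename(fp)), sep = "/")
          res <- tryCatch({
            if (format == "MOL2") read_mol2(path = fp)
            else {
              m <- read_pdbqt(path = fp)
              m <- perceive_bonds(m)
              assign_tripos_types(m)
            }
          }, error = function(e) e)
          if (inherits(res, "error")) {
            skipped[[length(skipped) + 1L]] <-
              data.frame(ligand_id = id, error = conditionMessage(res),
                         stringsAsFactors = FALSE)
          } else {
            res$name <- id
            mols[[id]] <- res
          }
        }
        if (!identical(cdir, coll)) unlink(cdir, recursive = TRUE)
      }
    }
  }
  list(molecules = mols, ids = names(mols),
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(ligand_id = character(), error = character()))
}

#' Consensus of per-scenario docking scores
#'
#' The arithmetic mean of a ligand's scores across the docking scenarios
#' of a screen; for a single scenario it is that score.
#'
#' @param scores non-empty numeric vector.
#' @return the mean score.
#' @export
consensus_score <- function(scores) {
  if (!length(scores)) stop("no scores to average", call. = FALSE)
  mean(scores)
}

#' Classify a screen output file as log or result
#'
#' File names containing any of \code{log}, \code{constraints},
#' \code{correspondingNames}, \code{descent}, \code{optimizer},
#' \code{plantsconfig} or \code{skippedligands} are log files; everything
#' else (docking poses, ranking/score tables) is a result file.
#'
#' @param filename non-empty file name(s).
#' @return \code{"log"} or \code{"result"} (vectorized).
#' @export
classify_output_file <- function(filename) {
  stopifnot(all(nzchar(filename)))
  pat <- "log|constraints|correspondingNames|descent|optimizer|plantsconfig|skippedligands"
  ifelse(grepl(pat, filename), "log", "result")
}

#' Mean score of the top-N ranked compounds (AVE_N)
#'
#' @param ranking a ranking data.frame with a \code{consensus} column, or a
#'   bare numeric score vector.
#' @param n how many of the most negative scores to average; if fewer
#'   entries exist, all are averaged with a warning.
#' @return mean of the n best (most negative) scores.
#' @export
top_n_average <- function(ranking, n) {
  stopifnot(n >= 1)
  scores <- if (is.data.frame(ranking)) ranking$consensus else as.numeric(ranking)
  if (!length(scores)) stop("empty ranking", call. = FALSE)
  if (length(scores) < n) {
    warning(sprintf("ranking has %d entries < n = %d; averaging all",
                    length(scores), n), call. = FALSE)
    n <- length(scores)
  }
  mean(sort(scores)[seq_len(n)])
}

# deterministic per-ligand seed from the global seed and the ligand id,
# independent of traversal order and worker scheduling
ligand_seed <- function(global_seed, ligand_id) {
  h <- as.numeric(global_seed) %% 2147483647
  for (c in utf8ToInt(ligand_id)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

#' Run a virtual screen
#'
#' Docks every library compound under every scenario of the control file,
#' computes the per-ligand consensus score, and writes results and logs to
#' separate output trees (\code{<output_root>/results},
#' \code{<output_root>/logs}) routed by \code{\link{classify_output_file}}.
#' Every ligand is docked with a seed derived from the global seed and its
#' id, so the ranking is identical for any worker count and any traversal
#' order.  A ligand whose docking fails is recorded in the
#' \code{skippedligands} log and excluded from the ranking; the screen
#' continues.
#'
#' @param cf a \code{\link{parse_control_file}} result (or an equivalent
#'   list built in code).
#' @param receptor optional receptor \code{\link{molecule}}; defaults to
#'   reading \code{cf$receptor}.
#' @param write_poses write the best pose of each ligand/scenario as MOL2
#'   (default TRUE).
#' @return the ranking data.frame (ligand_id, one score column per
#'   scenario, consensus, dock_time_s, convert_time_s), invisibly also
#'   written to \code{results/ranking.csv}; attributes \code{skipped} and
#'   \code{output_root}.
#' @export
run_screen <- function(cf, receptor = NULL, write_poses = TRUE) {
  if (!length(cf$scenarios)) stop("control file has no scenarios", call. = FALSE)
  if (is.null(receptor)) {
    if (is.null(cf$receptor)) stop("no receptor given", call. = FALSE)
    receptor <- read_mol2(path = cf$receptor)
  }
  res_dir <- file.path(cf$output_root, "results")
  log_dir <- file.path(cf$output_root, "logs")
  dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(log_dir, recursive = TRUE, showWarnings = FALSE)

  t_conv0 <- Sys.time()
  lib <- iterate_library(cf$library_root, cf$ligand_library_format)
  convert_time <- as.numeric(difftime(Sys.time(), t_conv0, units = "secs"))
  per_lig_convert <- convert_time / max(1L, length(lib$ids))

  dock_one <- function(id) {
    m <- lib$molecules[[id]]
    out <- list(ligand_id = id)
    t0 <- Sys.time()
    scores <- tryCatch({
      vapply(cf$scenarios, function(sc) {
        r <- run_aco(receptor, m, sc, seed = ligand_seed(cf$seed, id))
        if (write_poses) {
          posed <- set_coords(m, r$pose_xyz)
          fn <- sprintf("%s_%s_pose.mol2", gsub("/", "_", id), sc$name)
          write_mol2(posed, file.path(res_dir, fn))
        }
        r$score
      }, 0)
    }, error = function(e) e)
    out$dock_time <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (inherits(scores, "error")) {
      out$error <- conditionMessage(scores)
    } else {
      out$scores <- scores
    }
    out
  }

  runs <- if (cf$workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(lib$ids, dock_one, mc.cores = cf$workers)
  } else {
    lapply(lib$ids, dock_one)
  }

  failed <- Filter(function(r) !is.null(r$error), runs)
  ok <- Filter(function(r) is.null(r$error), runs)

  skipped_log <- file.path(log_dir, "skippedligands.txt")
  sk <- c(
    if (nrow(lib$skipped)) paste(lib$skipped$ligand_id, lib$skipped$error,
                                 sep = "\t"),
    vapply(failed, function(r) paste(r$ligand_id, r$error, sep = "\t"), ""))
  writeLines(as.character(sk), skipped_log)

  ranking <- if (length(ok)) {
    tab <- data.frame(ligand_id = vapply(ok, `[[`, "", "ligand_id"),
                      stringsAsFactors = FALSE)
    for (nm in names(cf$scenarios)) {
      tab[[nm]] <- vapply(ok, function(r) r$scores[[nm]], 0)
    }
    tab$consensus <- vapply(ok, function(r) consensus_score(r$scores), 0)
    tab$dock_time_s <- vapply(ok, `[[`, 0, "dock_time")
    tab$convert_time_s <- per_lig_convert
    tab[order(tab$consensus, tab$ligand_id), , drop = FALSE]
  } else {
    data.frame(ligand_id = character(), consensus = numeric(),
               dock_time_s = numeric(), convert_time_s = numeric())
  }
  rownames(ranking) <- NULL
  # ranking.csv holds only seed-deterministic columns (scores), so reruns
  # and different worker counts produce byte-identical files; wall times
  # are informational and go to timings.csv
  score_cols <- setdiff(names(ranking), c("dock_time_s", "convert_time_s"))
  utils::write.csv(ranking[, score_cols, drop = FALSE],
                   file.path(res_dir, "ranking.csv"), row.names = FALSE)
  utils::write.csv(ranking[, c("ligand_id", "dock_time_s", "convert_time_s")],
                   file.path(res_dir, "timings.csv"), row.names = FALSE)
  writeLines(sprintf("screen of %d ligands, %d scenarios, %d failed",
                     length(lib$ids), length(cf$scenarios), length(failed)),
             file.path(log_dir, "screen.log"))
  attr(ranking, "skipped") <- sk
  attr(ranking, "output_root") <- cf$output_root
  ranking
}
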