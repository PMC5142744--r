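# Self-contained statement-coverage harness.
#
# R side: every R/ source file is re-parsed and each statement inside a
# braced block (plus if/else arms and loop/function bodies) is rewritten to
# first invoke a hit-marker closure embedded literally in the AST; the
# rewritten definitions are injected into the loaded package namespace, the
# test suite is re-run, and coverage is hits / statements.
#
# C++ side: a temporary copy of the package is installed with
# "-O0 --coverage" so the same nested run leaves gcov counters next to the
# objects; gcov line results for the package's own sources are parsed
# (lines marked "#####"/"=====" are unexecuted; "-" lines are not
# executable).
#
# The nested run happens in a subprocess and excludes the acceptance test
# file: the coverage measurement cannot contain itself. Everything else in
# the suite runs there exactly as in a normal invocation.

cov_is_brace <- function(e) is.call(e) && identical(e[[1]], as.name("{"))

cov_skip_call <- function(e) {
  is.call(e) && is.name(e[[1]]) &&
    as.character(e[[1]]) %in% c("quote", "bquote", "substitute", "expression", "~")
}

# Rewrites `e`, appending one mark per counted statement; `state` holds the
# running statement count and the marker closure.
cov_instrument <- function(e, state) {
  wrap <- function(x) {
    state$n <- state$n + 1L
    as.call(list(as.name("{"),
                 as.call(list(as.name(".cov_mark_stmt"), state$n)),
                 cov_instrument(x, state)))
  }
  if (cov_is_brace(e)) {
    out <- as.list(e)
    for (i in seq_along(out)[-1]) out[[i]] <- wrap(out[[i]])
    return(as.call(out))
  }
  if (!is.call(e) || cov_skip_call(e)) return(e)
  head <- if (is.name(e[[1]])) as.character(e[[1]]) else ""
  out <- as.list(e)
  if (head == "if") {
    out[[2]] <- cov_instrument(out[[2]], state)
    out[[3]] <- wrap(out[[3]])
    if (length(out) == 4L) out[[4]] <- wrap(out[[4]])
  } else if (head == "for") {
    out[[3]] <- cov_instrument(out[[3]], state)
    out[[4]] <- wrap(out[[4]])
  } else if (head == "while") {
    out[[2]] <- cov_instrument(out[[2]], state)
    out[[3]] <- wrap(out[[3]])
  } else if (head == "repeat") {
    out[[2]] <- wrap(out[[2]])
  } else if (head == "function") {
    out[[3]] <- wrap(out[[3]])
    # a `function` AST node carries 4 slots (formals, body, srcref);
    # keep the arity with a NULL srcref or call inspection breaks
    out <- c(out[1:3], list(NULL))
  } else {
    for (i in seq_along(out)[-1]) {
      if (!identical(out[[i]], quote(expr = ))) {  # keep missing args
        out[i] <- list(cov_instrument(out[[i]], state))  # NULL-safe assign
      }
    }
  }
  as.call(out)
}

# Instruments every R source file of the package and injects the rewritten
# top-level function definitions into its (loaded) namespace. Returns the
# state environment whose $hits fills in as instrumented code runs.
cov_instrument_namespace <- function(pkg_root, package = "kmersieve") {
  state <- new.env(parent = emptyenv())
  state$n <- 0L
  state$hits <- logical(0)
  ns <- asNamespace(package)
  # instrumented closures are rebuilt in a scope layered over the
  # namespace so the `.cov_mark_stmt` symbol resolves without having to
  # add bindings to the sealed namespace itself
  wrapenv <- new.env(parent = ns)
  wrapenv$.cov_mark_stmt <- local({
    st <- state
    function(i) {
      st$hits[[i]] <- TRUE
      invisible(NULL)
    }
  })
  s3 <- get(".__S3MethodsTable__.", envir = ns)
  attached <- if (paste0("package:", package) %in% search()) {
    as.environment(paste0("package:", package))
  } else NULL
  for (f in list.files(file.path(pkg_root, "R"), pattern = "\\.R$",
                       full.names = TRUE)) {
    for (expr in parse(f, keep.source = FALSE)) {
      if (!(is.call(expr) && length(expr) == 3L &&
            (identical(expr[[1]], as.name("<-")) ||
             identical(expr[[1]], as.name("="))) &&
            is.name(expr[[2]]) &&
            is.call(expr[[3]]) && identical(expr[[3]][[1]], as.name("function")))) {
        next
      }
      nm <- as.character(expr[[2]])
      inst <- cov_instrument(expr[[3]], state)
      fun <- eval(inst, envir = wrapenv)
      if (bindingIsLocked(nm, ns)) unlockBinding(nm, ns)
      assign(nm, fun, envir = ns)
      if (exists(nm, envir = s3, inherits = FALSE)) {
        assign(nm, fun, envir = s3)
      }
      if (!is.null(attached) && exists(nm, envir = attached, inherits = FALSE)) {
        if (bindingIsLocked(nm, attached)) unlockBinding(nm, attached)
        assign(nm, fun, envir = attached)
      }
    }
  }
  state
}

cov_find_gcov <- function() {
  cc <- system2(file.path(R.home("bin"), "R"),
                c("CMD", "config", "CC"), stdout = TRUE)[[1]]
  cc <- strsplit(trimws(cc), " ")[[1]][[1]]
  cand <- sub("(gcc|cc)$", "gcov", cc)
  if (cand != cc && nzchar(Sys.which(cand))) return(cand)
  "gcov"
}

cov_parse_gcov <- function(gcov_file) {
  lines <- readLines(gcov_file, warn = FALSE)
  counts <- trimws(sub(":.*", "", lines))
  is_exec <- nzchar(counts) & counts != "-"
  is_hit <- is_exec & !counts %in% c("#####", "=====", "$$$$$")
  c(total = sum(is_exec), hit = sum(is_hit))
}

# Full measurement: instrumented install, nested suite run, gcov parse.
# Returns a list with r/c++/combined statement coverage.
measure_statement_coverage <- function(pkg_root,
                                       exclude_filter = "acceptance") {
  pkg_root <- normalizePath(pkg_root)
  stopifnot(file.exists(file.path(pkg_root, "DESCRIPTION")))
  work <- file.path(tempdir(), "covwork")
  unlink(work, recursive = TRUE)
  dir.create(file.path(work, "lib"), recursive = TRUE)
  src <- file.path(work, "pkg")
  dir.create(src)
  for (f in c("DESCRIPTION", "NAMESPACE", "R", "src", "inst", "exec")) {
    file.copy(file.path(pkg_root, f), src, recursive = TRUE)
  }
  # strip stale objects; add coverage compile flags
  unlink(list.files(file.path(src, "src"), "\\.(o|so|gcda|gcno)$",
                    full.names = TRUE))
  writeLines(c("PKG_CXXFLAGS = -O0 --coverage", "PKG_LIBS = --coverage"),
             file.path(src, "src", "Makevars"))
  rbin <- file.path(R.home("bin"), "R")
  inst_log <- system2(rbin, c("CMD", "INSTALL", "--no-docs", "--no-html",
                              "--no-help", "--no-test-load",
                              "-l", shQuote(file.path(work, "lib")),
                              shQuote(src)),
                      stdout = TRUE, stderr = TRUE)
  if (!file.exists(file.path(work, "lib", "kmersieve"))) {
    stop("instrumented install failed:\n",
         paste(utils::tail(inst_log, 20), collapse = "\n"))
  }

  runner <- file.path(work, "runner.R")
  result_file <- file.path(work, "r-coverage.rds")
  writeLines(c(
    sprintf(".libPaths(c(%s, .libPaths()))",
            deparse(file.path(work, "lib"))),
    "suppressPackageStartupMessages(library(kmersieve))",
    "suppressPackageStartupMessages(library(testthat))",
    sprintf("source(%s)",
            deparse(file.path(pkg_root, "tests", "testthat",
                              "helper-coverage.R"))),
    sprintf("state <- cov_instrument_namespace(%s)", deparse(pkg_root)),
    sprintf(paste0("res <- as.data.frame(test_dir(%s, filter = %s,",
                   " invert = TRUE, load_package = 'none',",
                   " stop_on_failure = FALSE, reporter = 'silent'))"),
            deparse(file.path(pkg_root, "tests", "testthat")),
            deparse(exclude_filter)),
    "hits <- state$hits",
    "length(hits) <- state$n",
    "hits[is.na(hits)] <- FALSE",
    sprintf(paste0("saveRDS(list(n = state$n, hit = sum(hits),",
                   " failed = sum(res$failed), error = sum(res$error)), %s)"),
            deparse(result_file))),
    runner)
  out <- system2(file.path(R.home("bin"), "Rscript"), shQuote(runner),
                 stdout = TRUE, stderr = TRUE)
  if (!file.exists(result_file)) {
    stop("coverage runner failed:\n", paste(utils::tail(out, 30), collapse = "\n"))
  }
  rres <- readRDS(result_file)

  gcov <- cov_find_gcov()
  srcdir <- file.path(src, "src")
  cpp_files <- list.files(srcdir, "\\.cpp$")
  owd <- setwd(srcdir)
  gcov_log <- tryCatch(
    system2(gcov, c("-o", ".", cpp_files), stdout = TRUE, stderr = TRUE),
    error = function(e) conditionMessage(e),
    finally = setwd(owd))
  ctotal <- 0L
  chit <- 0L
  for (f in cpp_files) {
    gf <- file.path(srcdir, paste0(f, ".gcov"))
    if (!file.exists(gf)) {
      stop("gcov produced no output for ", f, ":\n",
           paste(utils::tail(gcov_log, 10), collapse = "\n"))
    }
    v <- cov_parse_gcov(gf)
    ctotal <- ctotal + v[["total"]]
    chit <- chit + v[["hit"]]
  }

  list(r_statements = rres$n, r_hit = rres$hit,
       r_coverage = rres$hit / rres$n,
       cpp_lines = ctotal, cpp_hit = chit,
       cpp_coverage = if (ctotal > 0) chit / ctotal else NA_real_,
       nested_failures = rres$failed + rres$error,
       total_coverage = (rres$hit + chit) / (rres$n + ctotal))
}
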