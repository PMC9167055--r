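# Helper: small abstract signatures for merge tests.
sig_compartment <- function() {
  flatbrain:::new_signature(
    id = "comp",
    states = list(v = list(name = "v", dim = "voltage", init = NULL,
                           tau_sym = NULL, inf_sym = NULL)),
    requirements = c(itot = "current"),
    exposures = c(v = "v"),
    eval_statements = list(list(target = "itot", expr = quote(syn_i))),
    update_statements = list(list(state = "v", method = "fwd_euler",
                                  deriv = quote(itot / 1e-12),
                                  tau = NULL, inf = NULL)))
}
sig_synapse <- function() {
  flatbrain:::new_signature(
    id = "syn",
    constants = list(list(name = "erev", dim = "voltage", default = 0)),
    states = list(g = list(name = "g", dim = "conductance", init = NULL,
                           tau_sym = NULL, inf_sym = NULL)),
    requirements = c(v = "voltage"),
    exposures = c(i = "i"),
    eval_statements = list(list(target = "i", expr = quote(g * (erev - v)))),
    update_statements = list(list(state = "g", method = "fwd_euler",
                                  deriv = quote(-g / 0.005),
                                  tau = NULL, inf = NULL)))
}

test_that("leaf signatures carry states, requirements, handlers and order", {
  dyn <- flatbrain:::fb_builtin_dynamics("expOneSynapse", list(
    id = "s", gbase = "1nS", erev = "0mV", tauDecay = "5ms"))
  sig <- build_leaf_signature(dyn)
  expect_named(sig$states, "g")
  expect_true("v" %in% names(sig$requirements))
  expect_true("i" %in% names(sig$exposures))
  expect_length(sig$event_handlers, 1L)
  expect_identical(sig$event_handlers[[1]]$trigger$kind, "event")
  expect_length(sig$update_statements, 1L)
})

test_that("merging orders synapse eval before the summation that reads it", {
  merged <- merge_signatures(sig_compartment(), list(syn = sig_synapse()),
                             bindings = c("syn.v" = "v"))
  targets <- vapply(merged$eval_statements, `[[`, character(1), "target")
  expect_true(which(targets == "syn_i") < which(targets == "itot"))
  expect_true(flatbrain:::fb_sig_check(merged))
  # data signatures concatenated with per-mechanism contiguity
  expect_identical(unname(vapply(merged$states, `[[`, character(1), "name")),
                   c("v", "syn_g"))
})

test_that("two independent children keep document order (deterministic tie-break)", {
  child <- function() flatbrain:::new_signature(
    id = "ch",
    states = list(x = list(name = "x", dim = "none", init = NULL,
                           tau_sym = NULL, inf_sym = NULL)),
    exposures = c(y = "y"),
    eval_statements = list(list(target = "y", expr = quote(x + 1))))
  parent <- flatbrain:::new_signature(id = "p")
  m1 <- merge_signatures(parent, list(a = child(), b = child()))
  targets <- vapply(m1$eval_statements, `[[`, character(1), "target")
  expect_identical(targets, c("a_y", "b_y"))
  # regenerating gives the identical order
  m2 <- merge_signatures(parent, list(a = child(), b = child()))
  expect_identical(m1$eval_statements, m2$eval_statements)
})

test_that("unbound requirements and same-step cycles are errors", {
  expect_error(
    merge_signatures(sig_compartment(), list(syn = sig_synapse()),
                     bindings = c("syn.v" = "no_such_symbol")),
    class = "UnboundRequirement")
  # two mechanisms each requiring the other's same-step derived value
  mk <- function(id, out, inn) flatbrain:::new_signature(
    id = id, requirements = stats::setNames("none", inn),
    exposures = stats::setNames(out, out),
    eval_statements = list(list(target = out,
                                expr = bquote(.(as.name(inn)) + 1))))
  expect_error(
    merge_signatures(flatbrain:::new_signature(id = "p"),
                     list(a = mk("a", "ya", "yb"), b = mk("b", "yb", "ya")),
                     bindings = c("a.yb" = "b_yb", "b.ya" = "a_ya")),
    class = "CyclicExposureDependency")
})

test_that("eval-before-use holds after merging random mechanism DAGs", {
  set.seed(42)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    children <- list()
    for (i in seq_len(k)) {
      # child i exposes y_i computed from its own state and optionally the
      # exposure of an earlier child
      dep <- if (i > 1 && stats::runif(1) < 0.6) sample(seq_len(i - 1), 1) else NA
      expr <- if (is.na(dep)) quote(x * 2)
              else bquote(x + .(as.name("need")))
      reqs <- if (is.na(dep)) character(0) else c(need = "none")
      children[[paste0("m", i)]] <- flatbrain:::new_signature(
        id = paste0("m", i),
        states = list(x = list(name = "x", dim = "none", init = NULL,
                               tau_sym = NULL, inf_sym = NULL)),
        requirements = reqs,
        exposures = c(y = "y"),
        eval_statements = list(list(target = "y", expr = expr)))
      if (!is.na(dep)) {
        attr(children[[paste0("m", i)]], "dep") <- dep
      }
    }
    bindings <- character(0)
    for (i in seq_len(k)) {
      dep <- attr(children[[paste0("m", i)]], "dep")
      if (!is.null(dep)) {
        bindings[paste0("m", i, ".need")] <- paste0("m", dep, "_y")
      }
    }
    # shuffle child order so the topological sort has work to do
    ord <- sample(k)
    merged <- merge_signatures(flatbrain:::new_signature(id = "p"),
                               children[ord], bindings)
    expect_true(flatbrain:::fb_sig_check(merged))
  }
})
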