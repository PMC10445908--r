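#' Virtual simulation clock
#'
#' All timed behavior in the simulator (stage settling, fluidics dynamics,
#' incubation periods, focal-surface drift) elapses on this clock rather
#' than on wall time, so a multi-hour experiment simulates in seconds.
#' Devices with time-dependent state register `on_advance` hooks which are
#' invoked, in registration order, on every [SimClock]`$advance()` call.
#'
#' @export
SimClock <- R6::R6Class("SimClock",
  public = list(
    #' @field now Current virtual time in seconds (nondecreasing).
    now = 0,

    #' @description Create a clock starting at t = 0 s.
    initialize = function() {
      self$now <- 0
      private$hooks <- list()
    },

    #' @description Register a hook called as `fn(dt)` on every advance.
    #' @param fn Function of one argument (the time step in seconds).
    #' @param name Optional hook name (replaces an existing hook of the
    #'   same name, so re-wiring a device does not double-register it).
    on_advance = function(fn, name = NULL) {
      stopifnot(is.function(fn))
      if (is.null(name)) name <- sprintf(".anon%03d", length(private$hooks) + 1L)
      private$hooks[[name]] <- fn
      invisible(self)
    },

    #' @description Advance virtual time by `dt` seconds and run all hooks.
    #' @param dt Nonnegative time step in seconds.
    advance = function(dt) {
      if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt < 0) {
        stop("SimClock$advance: dt must be a nonnegative number, got ", dt)
      }
      if (dt == 0) return(invisible(self))
      self$now <- self$now + dt
      for (fn in private$hooks) fn(dt)
      invisible(self)
    }
  ),
  private = list(hooks = NULL)
)
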