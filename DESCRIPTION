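Package: reefplan
Title: Facility Location, Sizing and Growth-Time Planning for Cultivated-Resource Restoration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-support tool for planning land-based aquaculture of a
    cultivated resource (the motivating application is coral propagation for
    large-scale reef restoration). Converts reef records into annual coral
    demand via restoration-atoll geometry, aggregates reefs into
    vessel-capacity-respecting clusters by a north-to-south sweep, and finds
    the minimum-cost number, placement and sizing of growth facilities
    together with the optimal in-facility growth (residence) time. Growth
    time drives post-deployment survival through truncated parametric
    survival curves, and facility floor area follows from Little's law. The
    optimizer is a two-stage scheme: an outer grid search over growth time
    wrapping an inner mixed-integer linear program with integer vessel trips,
    binary facility-opening decisions and big-M linking. Includes an exact
    enumeration oracle for small instances, scripted sensitivity studies
    (reef subsets, cost scaling, maximum survival, survival functional
    forms), and a synthetic reef-field generator so everything runs without
    proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
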