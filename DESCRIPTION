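Package: fesloop
Title: Closed-Loop Functional Electrical Stimulation Simulator
Version: 0.1.0
Authors@R: person("fesloop", "maintainers", email = "fesloop@example.org",
    role = c("aut", "cre"))
Description: Hardware-free simulator and control library for a four-channel
    closed-loop functional electrical stimulation (FES) system: biphasic
    stimulation pulse-train scheduling, boost-converter voltage dynamics,
    discrete PID control with conditional-integration anti-windup and output
    saturation, agonist/antagonist muscle-selector routing, complementary-filter
    joint-angle estimation from inertial data, and a synthetic two
    degree-of-freedom ankle plant with motor-threshold deadzone, recruitment
    saturation and activation lag, so that closed-loop ankle protocols
    (dorsiflexion, plantar flexion, inversion, eversion) can be reproduced and
    tested at desk scale without hardware or human subjects.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
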