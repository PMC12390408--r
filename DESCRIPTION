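Package: freezekin
Title: Foot-Mounted IMU Gait Analysis with Zero-Velocity-Update Dead Reckoning
Version: 0.1.0
Authors@R:
    person("freezekin", "maintainers", email = "freezekin@example.org",
           role = c("aut", "cre"))
Description: Spatiotemporal gait analysis from foot-mounted inertial
    measurement units (IMUs). Detects heel strike, toe strike, heel off and
    toe off from the sagittal angular-velocity signal, segments the four
    gait phases (loading response, midstance, pre-swing, swing), and
    computes stride time, cadence, the Gait Phase Quality Index (GPQI),
    zero-velocity-update (ZUPT) stride length, walking speed and foot
    clearance landmarks (Max1, Min, Max2). Includes Bland-Altman method
    agreement against a reference marker trajectory, the group-comparison
    statistics used in clinical gait studies (Shapiro-Wilk gating into
    Mann-Whitney U or t tests), and a ground-truthed synthetic gait
    generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
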