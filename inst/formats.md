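# File formats (schema version 1)

## Tracked-spot CSV (input/output)

One row per localisation. Required columns (case-insensitive; TrackMate
exports with up to three extra header rows below the column names are
detected and skipped):

| column       | type    | unit |
|--------------|---------|------|
| `TRACK_ID`   | id      |      |
| `FRAME`      | integer |      |
| `POSITION_X` | numeric | um   |
| `POSITION_Y` | numeric | um   |
| `POSITION_T` | numeric | s    |

Frame gaps are allowed (no gap closing upstream) and preserved; duplicate
`(TRACK_ID, FRAME)` pairs are rejected. `POSITION_T` is optional when a
frame interval is supplied.

## Per-track metrics CSV (`analyze`)

One row per track: `track_id`, `n_frames`, `mean_step_nm`, `avg_fluct_nm`,
`max_fluct_nm`, `total_displacement_um`, `alpha_app`, `r_squared`, `D_app`
(um^2/s), `log10_Dapp`, `sigma_nm`, `alpha_ok`, `dapp_flags`.

## Kinematics CSV (`kinematics`)

`track_id`, `max_theta_deg`, `vacf`, `va_corr`, `ps_area` (rad^2/s^3).

## Sweep CSV (`sweep`), long format

`log10D`, `diameter` (um), `alpha`, `ratio_Dapp`, `ratio_alpha`, `n_teth`,
`n_unteth`. One row per Sobol point per exponent regime.

## Heatmap CSV (`heatmap`), long format

`log10D`, `diameter` (cell centres), `alpha_regime`, `ratio_Dapp`,
`ratio_alpha`, `n` (points per cell; 0 rows carry NA ratios).

## Comparison CSV (`compare`)

`group_x`, `group_y`, `test`, `statistic` (U), `p_value`, `cliffs_delta`,
`effect_label`, `annotation`, `n_x`, `n_y`.

## Masks

ASCII PGM (`P1`/`P2`) or headerless CSV matrices; 0 = background, positive
integers = object labels (a 0/1 mask is connected-component labeled).

## Provenance sidecar (JSON)

`config` (full parameter list), `config_hash`, `seed`, `package`,
`version`, plus artefact-specific extras (e.g. `filter_audit`,
`localization_sigma_nm`). Written next to every CLI artefact.
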