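# terrestrial gamma-ray background spectrum v1
# units keV relative_intensity
# normalization relative (absolute flux is set by the source strength)
# Representative ambient terrestrial spectrum: discrete K/U/Th-series lines
# (15% of the flux) over a scatter-dominated continuum (85%, ~E^-1.7 per
# unit energy, 30 - 2700 keV), as measured ambient spectra are dominated by
# build-up from Compton-scattered photons. The continuum slope is anchored
# so that the mean energy of the secondary electrons recorded in the
# sensitive well reproduces the printed 74 keV; only the integral flux is
# site-constrained. Substitute a measured spectrum file to change the shape.
# columns E_low_keV E_high_keV intensity
239 239 0.0085714
352 352 0.0114286
583 583 0.0085714
609 609 0.0171429
911 911 0.0085714
969 969 0.0042857
1120 1120 0.0085714
1461 1461 0.0571429
1764 1764 0.0085714
2204 2204 0.0028571
2615 2615 0.0142857
30.000 40.495 0.1682062
40.495 54.662 0.1363465
54.662 73.785 0.1105213
73.785 99.599 0.0895876
99.599 134.44 0.0726190
134.44 181.48 0.0588643
181.48 244.96 0.0477149
244.96 330.66 0.0386773
330.66 446.34 0.0313515
446.34 602.49 0.0254133
602.49 813.27 0.0205998
813.27 1097.8 0.0166980
1097.8 1481.8 0.0135352
1481.8 2000.2 0.0109716
2000.2 2700.0 0.0088935
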