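Placeholder for the published study's deposited isoscape products, which
are third-party supplementary downloads and are not redistributed here.

To run the published-assessment reproduction, place in this directory:

  rf_prediction.asc / rf_prediction.asc.prj  - deposited RF isoscape,
      converted to ESRI ASCII grid (WGS84)
  rf_sd.asc / rf_sd.asc.prj                  - its spatial-uncertainty map
  sites_sm2.csv                              - compiled archaeological /
      modern site table (columns: site, longitude, latitude, material,
      period, sr_ratio, source, coord_provenance)

then reinstall the package and run reproduce_published_assessment() or the
corresponding acceptance test.
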