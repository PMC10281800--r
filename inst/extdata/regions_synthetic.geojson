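{
  "type": "FeatureCollection",
  "description": "Synthetic, simplified region polygons for the migration corridor between the UK and central Africa. Rectangular approximations for testing and simulation; not digitised from any map.",
  "features": [
    {"type": "Feature", "properties": {"name": "breeding_area"},
     "geometry": {"type": "Polygon", "coordinates": [[[-8.0, 50.0], [2.0, 50.0], [2.0, 59.5], [-8.0, 59.5], [-8.0, 50.0]]]}},
    {"type": "Feature", "properties": {"name": "iberia"},
     "geometry": {"type": "Polygon", "coordinates": [[[-10.0, 36.0], [3.0, 36.0], [3.0, 44.0], [-10.0, 44.0], [-10.0, 36.0]]]}},
    {"type": "Feature", "properties": {"name": "italy"},
     "geometry": {"type": "Polygon", "coordinates": [[[6.0, 36.5], [19.0, 36.5], [19.0, 46.5], [6.0, 46.5], [6.0, 36.5]]]}},
    {"type": "Feature", "properties": {"name": "sahara"},
     "geometry": {"type": "Polygon", "coordinates": [[[-17.0, 16.0], [35.0, 16.0], [35.0, 30.0], [-17.0, 30.0], [-17.0, 16.0]]]}},
    {"type": "Feature", "properties": {"name": "west_africa"},
     "geometry": {"type": "Polygon", "coordinates": [[[-17.0, 4.0], [10.0, 4.0], [10.0, 16.0], [-17.0, 16.0], [-17.0, 4.0]]]}},
    {"type": "Feature", "properties": {"name": "wintering_grounds"},
     "geometry": {"type": "Polygon", "coordinates": [[[10.0, -6.0], [30.0, -6.0], [30.0, 6.0], [10.0, 6.0], [10.0, -6.0]]]}}
  ]
}
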