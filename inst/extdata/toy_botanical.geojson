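{
 "type": "FeatureCollection",
 "features": [
  {
   "type": "Feature",
   "properties": {
    "region_name": "Borneo"
   },
   "geometry": {
    "type": "Polygon",
    "coordinates": [
     [
      [
       109,
       -4
      ],
      [
       119,
       -4
      ],
      [
       119,
       7
      ],
      [
       109,
       7
      ],
      [
       109,
       -4
      ]
     ]
    ]
   }
  },
  {
   "type": "Feature",
   "properties": {
    "region_name": "Peru"
   },
   "geometry": {
    "type": "Polygon",
    "coordinates": [
     [
      [
       -81,
       -18
      ],
      [
       -69,
       -18
      ],
      [
       -69,
       0
      ],
      [
       -81,
       0
      ],
      [
       -81,
       -18
      ]
     ]
    ]
   }
  },
  {
   "type": "Feature",
   "properties": {
    "region_name": "Madagascar"
   },
   "geometry": {
    "type": "Polygon",
    "coordinates": [
     [
      [
       43,
       -26
      ],
      [
       51,
       -26
      ],
      [
       51,
       -12
      ],
      [
       43,
       -12
      ],
      [
       43,
       -26
      ]
     ]
    ]
   }
  },
  {
   "type": "Feature",
   "properties": {
    "region_name": "Brazil North"
   },
   "geometry": {
    "type": "Polygon",
    "coordinates": [
     [
      [
       -74,
       -10
      ],
      [
       -46,
       -10
      ],
      [
       -46,
       5
      ],
      [
       -74,
       5
      ],
      [
       -74,
       -10
      ]
     ]
    ]
   }
  },
  {
   "type": "Feature",
   "properties": {
    "region_name": "Brazil Northeast"
   },
   "geometry": {
    "type": "Polygon",
    "coordinates": [
     [
      [
       -48,
       -18
      ],
      [
       -35,
       -18
      ],
      [
       -35,
       -2
      ],
      [
       -48,
       -2
      ],
      [
       -48,
       -18
      ]
     ]
    ]
   }
  },
  {
   "type": "Feature",
   "properties": {
    "region_name": "New Guinea"
   },
   "geometry": {
    "type": "Polygon",
    "coordinates": [
     [
      [
       131,
       -11
      ],
      [
       156,
       -11
      ],
      [
       156,
       0
      ],
      [
       131,
       0
      ],
      [
       131,
       -11
      ]
     ]
    ]
   }
  },
  {
   "type": "Feature",
   "properties": {
    "region_name": "Sumatera"
   },
   "geometry": {
    "type": "Polygon",
    "coordinates": [
     [
      [
       95,
       -6
      ],
      [
       106,
       -6
      ],
      [
       106,
       6
      ],
      [
       95,
       6
      ],
      [
       95,
       -6
      ]
     ]
    ]
   }
  },
  {
   "type": "Feature",
   "properties": {
    "region_name": "Jawa"
   },
   "geometry": {
    "type": "Polygon",
    "coordinates": [
     [
      [
       105,
       -9
      ],
      [
       115,
       -9
      ],
      [
       115,
       -5
      ],
      [
       105,
       -5
      ],
      [
       105,
       -9
      ]
     ]
    ]
   }
  },
  {
   "type": "Feature",
   "properties": {
    "region_name": "Thailand"
   },
   "geometry": {
    "type": "Polygon",
    "coordinates": [
     [
      [
       97,
       6
      ],
      [
       106,
       6
      ],
      [
       106,
       20
      ],
      [
       97,
       20
      ],
      [
       97,
       6
      ]
     ]
    ]
   }
  },
  {
   "type": "Feature",
   "properties": {
    "region_name": "India"
   },
   "geometry": {
    "type": "Polygon",
    "coordinates": [
     [
      [
       68,
       8
      ],
      [
       97,
       8
      ],
      [
       97,
       35
      ],
      [
       68,
       35
      ],
      [
       68,
       8
      ]
     ]
    ]
   }
  },
  {
   "type": "Feature",
   "properties": {
    "region_name": "Queensland"
   },
   "geometry": {
    "type": "Polygon",
    "coordinates": [
     [
      [
       138,
       -29
      ],
      [
       154,
       -29
      ],
      [
       154,
       -10
      ],
      [
       138,
       -10
      ],
      [
       138,
       -29
      ]
     ]
    ]
   }
  },
  {
   "type": "Feature",
   "properties": {
    "region_name": "Tasmania"
   },
   "geometry": {
    "type": "Polygon",
    "coordinates": [
     [
      [
       144,
       -44
      ],
      [
       149,
       -44
      ],
      [
       149,
       -40
      ],
      [
       144,
       -40
      ],
      [
       144,
       -44
      ]
     ]
    ]
   }
  },
  {
   "type": "Feature",
   "properties": {
    "region_name": "Mexico Central"
   },
   "geometry": {
    "type": "Polygon",
    "coordinates": [
     [
      [
       -104,
       17
      ],
      [
       -96,
       17
      ],
      [
       -96,
       22
      ],
      [
       -104,
       22
      ],
      [
       -104,
       17
      ]
     ]
    ]
   }
  },
  {
   "type": "Feature",
   "properties": {
    "region_name": "China Southeast"
   },
   "geometry": {
    "type": "Polygon",
    "coordinates": [
     [
      [
       108,
       21
      ],
      [
       123,
       21
      ],
      [
       123,
       32
      ],
      [
       108,
       32
      ],
      [
       108,
       21
      ]
     ]
    ]
   }
  },
  {
   "type": "Feature",
   "properties": {
    "region_name": "Colombia"
   },
   "geometry": {
    "type": "Polygon",
    "coordinates": [
     [
      [
       -79,
       -4
      ],
      [
       -67,
       -4
      ],
      [
       -67,
       12
      ],
      [
       -79,
       12
      ],
      [
       -79,
       -4
      ]
     ]
    ]
   }
  }
 ]
}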