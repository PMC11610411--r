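{
 "type": "FeatureCollection",
 "features": [
  {
   "type": "Feature",
   "properties": {
    "region_name": "Brazil"
   },
   "geometry": {
    "type": "Polygon",
    "coordinates": [
     [
      [
       -74,
       -33
      ],
      [
       -35,
       -33
      ],
      [
       -35,
       5
      ],
      [
       -74,
       5
      ],
      [
       -74,
       -33
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
  },
  {
   "type": "Feature",
   "properties": {
    "region_name": "Brunei"
   },
   "geometry": {
    "type": "Polygon",
    "coordinates": [
     [
      [
       114,
       4
      ],
      [
       115.5,
       4
      ],
      [
       115.5,
       5
      ],
      [
       114,
       5
      ],
      [
       114,
       4
      ]
     ]
    ]
   }
  },
  {
   "type": "Feature",
   "properties": {
    "region_name": "Indonesia"
   },
   "geometry": {
    "type": "Polygon",
    "coordinates": [
     [
      [
       95,
       -11
      ],
      [
       141,
       -11
      ],
      [
       141,
       6
      ],
      [
       95,
       6
      ],
      [
       95,
       -11
      ]
     ]
    ]
   }
  },
  {
   "type": "Feature",
   "properties": {
    "region_name": "Malaysia"
   },
   "geometry": {
    "type": "Polygon",
    "coordinates": [
     [
      [
       100,
       1
      ],
      [
       119,
       1
      ],
      [
       119,
       7
      ],
      [
       100,
       7
      ],
      [
       100,
       1
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
    "region_name": "China"
   },
   "geometry": {
    "type": "Polygon",
    "coordinates": [
     [
      [
       73,
       18
      ],
      [
       135,
       18
      ],
      [
       135,
       53
      ],
      [
       73,
       53
      ],
      [
       73,
       18
      ]
     ]
    ]
   }
  },
  {
   "type": "Feature",
   "properties": {
    "region_name": "Australia"
   },
   "geometry": {
    "type": "Polygon",
    "coordinates": [
     [
      [
       113,
       -44
      ],
      [
       154,
       -44
      ],
      [
       154,
       -10
      ],
      [
       113,
       -10
      ],
      [
       113,
       -44
      ]
     ]
    ]
   }
  },
  {
   "type": "Feature",
   "properties": {
    "region_name": "Mexico"
   },
   "geometry": {
    "type": "Polygon",
    "coordinates": [
     [
      [
       -117,
       14
      ],
      [
       -86,
       14
      ],
      [
       -86,
       33
      ],
      [
       -117,
       33
      ],
      [
       -117,
       14
      ]
     ]
    ]
   }
  },
  {
   "type": "Feature",
   "properties": {
    "region_name": "Papua New Guinea"
   },
   "geometry": {
    "type": "Polygon",
    "coordinates": [
     [
      [
       141,
       -12
      ],
      [
       156,
       -12
      ],
      [
       156,
       -1
      ],
      [
       141,
       -1
      ],
      [
       141,
       -12
      ]
     ]
    ]
   }
  },
  {
   "type": "Feature",
   "properties": {
    "region_name": "France"
   },
   "geometry": {
    "type": "Polygon",
    "coordinates": [
     [
      [
       -5,
       42
      ],
      [
       8,
       42
      ],
      [
       8,
       51
      ],
      [
       -5,
       51
      ],
      [
       -5,
       42
      ]
     ]
    ]
   }
  },
  {
   "type": "Feature",
   "properties": {
    "region_name": "Japan"
   },
   "geometry": {
    "type": "Polygon",
    "coordinates": [
     [
      [
       129,
       31
      ],
      [
       146,
       31
      ],
      [
       146,
       45
      ],
      [
       129,
       45
      ],
      [
       129,
       31
      ]
     ]
    ]
   }
  }
 ]
}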