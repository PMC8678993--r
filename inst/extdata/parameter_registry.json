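[{"name":"1658","description":"protein distribution (amide I)","numerator":{"name":"1658","lo":1634,"hi":1682,"anchor_hw":8,"mode":"area"},"denominator":null},{"name":"1635/1658","description":"beta-sheet to alpha-helix ratio","numerator":{"name":"1635n","lo":1627,"hi":1643,"anchor_hw":4,"mode":"area"},"denominator":{"name":"1658n","lo":1650,"hi":1666,"anchor_hw":4,"mode":"area"}},{"name":"2800-3000","description":"lipid distribution","numerator":{"name":"2800-3000","lo":2800,"hi":3000,"anchor_hw":8,"mode":"area"},"denominator":null},{"name":"2924/2955","description":"lipid saturation / chain length and branching","numerator":{"name":"2924n","lo":2912,"hi":2936,"anchor_hw":4,"mode":"area"},"denominator":{"name":"2955n","lo":2943,"hi":2967,"anchor_hw":4,"mode":"area"}},{"name":"1080","description":"phosphate-containing compounds","numerator":{"name":"1080","lo":1056,"hi":1104,"anchor_hw":8,"mode":"area"},"denominator":null},{"name":"1240","description":"phosphate-containing compounds","numerator":{"name":"1240","lo":1216,"hi":1264,"anchor_hw":8,"mode":"area"},"denominator":null},{"name":"1360-1480","description":"lipids, cholesterol and cholesterol esters","numerator":{"name":"1360-1480","lo":1360,"hi":1480,"anchor_hw":8,"mode":"area"},"denominator":null},{"name":"1740","description":"phospholipids, cholesterol esters, ketone bodies","numerator":{"name":"1740","lo":1716,"hi":1764,"anchor_hw":8,"mode":"area"},"denominator":null},{"name":"2800-3000/1658","description":"lipid to protein","numerator":{"name":"2800-3000","lo":2800,"hi":3000,"anchor_hw":8,"mode":"area"},"denominator":{"name":"1658","lo":1634,"hi":1682,"anchor_hw":8,"mode":"area"}},{"name":"1080/1658","description":"phosphates to protein","numerator":{"name":"1080","lo":1056,"hi":1104,"anchor_hw":8,"mode":"area"},"denominator":{"name":"1658","lo":1634,"hi":1682,"anchor_hw":8,"mode":"area"}},{"name":"1240/1658","description":"phosphates to protein","numerator":{"name":"1240","lo":1216,"hi":1264,"anchor_hw":8,"mode":"area"},"denominator":{"name":"1658","lo":1634,"hi":1682,"anchor_hw":8,"mode":"area"}},{"name":"1740/1658","description":"carbonyl esters to protein","numerator":{"name":"1740","lo":1716,"hi":1764,"anchor_hw":8,"mode":"area"},"denominator":{"name":"1658","lo":1634,"hi":1682,"anchor_hw":8,"mode":"area"}},{"name":"1360-1480/1658","description":"methyl/methylene compounds to protein","numerator":{"name":"1360-1480","lo":1360,"hi":1480,"anchor_hw":8,"mode":"area"},"denominator":{"name":"1658","lo":1634,"hi":1682,"anchor_hw":8,"mode":"area"}},{"name":"1080/2800-3000","description":"phosphates to lipid","numerator":{"name":"1080","lo":1056,"hi":1104,"anchor_hw":8,"mode":"area"},"denominator":{"name":"2800-3000","lo":2800,"hi":3000,"anchor_hw":8,"mode":"area"}},{"name":"1240/2800-3000","description":"phosphates to lipid","numerator":{"name":"1240","lo":1216,"hi":1264,"anchor_hw":8,"mode":"area"},"denominator":{"name":"2800-3000","lo":2800,"hi":3000,"anchor_hw":8,"mode":"area"}},{"name":"1740/2800-3000","description":"carbonyl esters to lipid","numerator":{"name":"1740","lo":1716,"hi":1764,"anchor_hw":8,"mode":"area"},"denominator":{"name":"2800-3000","lo":2800,"hi":3000,"anchor_hw":8,"mode":"area"}},{"name":"1360-1480/2800-3000","description":"methyl/methylene compounds to lipid","numerator":{"name":"1360-1480","lo":1360,"hi":1480,"anchor_hw":8,"mode":"area"},"denominator":{"name":"2800-3000","lo":2800,"hi":3000,"anchor_hw":8,"mode":"area"}}]
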