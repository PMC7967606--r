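parcel_id,year_built,appraised_value,grade
Property 1,1985,156000,B
Property 2,1971,275000,B
Property 3,1965,130000,C
Property 4,1961,70000,C-
Property 5,1955,270000,B-
Property 6,1951,145000,C--
Property 7,1943,60000,D+
Property 8,1932,265000,A-
Property 9,1927,130000,C++
Property 10,1910,50000,D
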