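session,season,phase,species_id,density,tfi
autumn_1999,autumn,low,carrion_crow,14.9,2.2
autumn_1999,autumn,low,common_buzzard,3.3,0.6
autumn_1999,autumn,low,red_kite,2.9,0.1
autumn_1999,autumn,low,kestrel,0.2,0.2
autumn_1999,autumn,low,domestic_cat_day,0.5,0.2
autumn_1999,autumn,low,hen_harrier,0.4,0
autumn_1999,autumn,low,red_fox,0.1,0.1
autumn_1999,autumn,low,wildcat,0,0
autumn_1999,autumn,low,long_eared_owl,0.3,0
autumn_1999,autumn,low,badger,0,0
autumn_1999,autumn,low,domestic_cat_night,1.6,0.6
autumn_2003,autumn,high,carrion_crow,19.4,2.9
autumn_2003,autumn,high,common_buzzard,11,2
autumn_2003,autumn,high,red_kite,2,1.2
autumn_2003,autumn,high,kestrel,5,0.2
autumn_2003,autumn,high,domestic_cat_day,0.5,0.2
autumn_2003,autumn,high,hen_harrier,0.2,0
autumn_2003,autumn,high,red_fox,0.8,0.4
autumn_2003,autumn,high,wildcat,1.6,0.6
autumn_2003,autumn,high,long_eared_owl,1,0.1
autumn_2003,autumn,high,badger,0.1,0.1
autumn_2003,autumn,high,domestic_cat_night,2.1,0.7
spring_2007,spring,low,carrion_crow,3.1,0.4
spring_2007,spring,low,common_buzzard,1.2,0.2
spring_2007,spring,low,red_kite,0.3,0.1
spring_2007,spring,low,kestrel,0.3,0
spring_2007,spring,low,domestic_cat_day,0.5,0.2
spring_2007,spring,low,hen_harrier,0,0
spring_2007,spring,low,red_fox,0.5,0.3
spring_2007,spring,low,wildcat,0.4,0.1
spring_2007,spring,low,long_eared_owl,0,0
spring_2007,spring,low,badger,0.1,0.1
spring_2007,spring,low,domestic_cat_night,1.3,0.5
autumn_2008,autumn,high,carrion_crow,28.6,4.2
autumn_2008,autumn,high,common_buzzard,16.1,2.9
autumn_2008,autumn,high,red_kite,2.8,2
autumn_2008,autumn,high,kestrel,8.5,0.2
autumn_2008,autumn,high,domestic_cat_day,0.9,0.3
autumn_2008,autumn,high,hen_harrier,0.1,0
autumn_2008,autumn,high,red_fox,0.4,0.2
autumn_2008,autumn,high,wildcat,0.5,0.2
autumn_2008,autumn,high,long_eared_owl,0.1,0
autumn_2008,autumn,high,badger,0,0
autumn_2008,autumn,high,domestic_cat_night,1.6,0.6
autumn_2010,autumn,low,carrion_crow,12.9,1.9
autumn_2010,autumn,low,common_buzzard,1.4,0.3
autumn_2010,autumn,low,red_kite,1,0.1
autumn_2010,autumn,low,kestrel,0.4,0.1
autumn_2010,autumn,low,domestic_cat_day,0.3,0.1
autumn_2010,autumn,low,hen_harrier,0.1,0
autumn_2010,autumn,low,red_fox,3,1.5
autumn_2010,autumn,low,wildcat,0.8,0.3
autumn_2010,autumn,low,long_eared_owl,0,0
autumn_2010,autumn,low,badger,0.1,0.1
autumn_2010,autumn,low,domestic_cat_night,0.9,0.3
autumn_2012,autumn,high,carrion_crow,7.9,1.2
autumn_2012,autumn,high,common_buzzard,9.4,1.7
autumn_2012,autumn,high,red_kite,3,0.3
autumn_2012,autumn,high,kestrel,1.4,0.2
autumn_2012,autumn,high,domestic_cat_day,1.2,0.4
autumn_2012,autumn,high,hen_harrier,0.2,0
autumn_2012,autumn,high,red_fox,4.9,2.4
autumn_2012,autumn,high,wildcat,0.7,0.3
autumn_2012,autumn,high,long_eared_owl,0.4,0
autumn_2012,autumn,high,badger,0.2,0.2
autumn_2012,autumn,high,domestic_cat_night,0.6,0.2
spring_2014,spring,low,carrion_crow,3.6,0.5
spring_2014,spring,low,common_buzzard,0.7,0.1
spring_2014,spring,low,red_kite,0.1,0.1
spring_2014,spring,low,kestrel,0.4,0
spring_2014,spring,low,domestic_cat_day,0.3,0.1
spring_2014,spring,low,hen_harrier,0,0
spring_2014,spring,low,red_fox,2.8,1.3
spring_2014,spring,low,wildcat,0.6,0.2
spring_2014,spring,low,long_eared_owl,0,0
spring_2014,spring,low,badger,0.1,0.1
spring_2014,spring,low,domestic_cat_night,0.9,0.3
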