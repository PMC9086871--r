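kind	name	state	county
state	Alabama	AL	
state	Alaska	AK	
state	Arizona	AZ	
state	Arkansas	AR	
state	California	CA	
state	Colorado	CO	
state	Connecticut	CT	
state	Delaware	DE	
state	District of Columbia	DC	
state	Florida	FL	
state	Georgia	GA	
state	Hawaii	HI	
state	Idaho	ID	
state	Illinois	IL	
state	Indiana	IN	
state	Iowa	IA	
state	Kansas	KS	
state	Kentucky	KY	
state	Louisiana	LA	
state	Maine	ME	
state	Maryland	MD	
state	Massachusetts	MA	
state	Michigan	MI	
state	Minnesota	MN	
state	Mississippi	MS	
state	Missouri	MO	
state	Montana	MT	
state	Nebraska	NE	
state	Nevada	NV	
state	New Hampshire	NH	
state	New Jersey	NJ	
state	New Mexico	NM	
state	New York	NY	
state	North Carolina	NC	
state	North Dakota	ND	
state	Ohio	OH	
state	Oklahoma	OK	
state	Oregon	OR	
state	Pennsylvania	PA	
state	Rhode Island	RI	
state	South Carolina	SC	
state	South Dakota	SD	
state	Tennessee	TN	
state	Texas	TX	
state	Utah	UT	
state	Vermont	VT	
state	Virginia	VA	
state	Washington	WA	
state	West Virginia	WV	
state	Wisconsin	WI	
state	Wyoming	WY	
county	Maricopa County	AZ	
county	Alameda County	CA	
county	Los Angeles County	CA	
county	Orange County	CA	
county	Riverside County	CA	
county	Sacramento County	CA	
county	San Bernardino County	CA	
county	San Diego County	CA	
county	San Francisco County	CA	
county	San Mateo County	CA	
county	Broward County	FL	
county	Duval County	FL	
county	Hillsborough County	FL	
county	Miami-Dade County	FL	
county	Orange County	FL	
county	Palm Beach County	FL	
county	Pinellas County	FL	
county	Cobb County	GA	
county	DeKalb County	GA	
county	Fulton County	GA	
county	Gwinnett County	GA	
county	Cook County	IL	
county	Sangamon County	IL	
county	Marion County	IN	
county	East Baton Rouge Parish	LA	
county	Orleans Parish	LA	
county	Baltimore City	MD	
county	Montgomery County	MD	
county	Prince George's County	MD	
county	Suffolk County	MA	
county	Hampden County	MA	
county	Wayne County	MI	
county	Hennepin County	MN	
county	Clark County	NV	
county	Essex County	NJ	
county	Hudson County	NJ	
county	Bronx County	NY	
county	Kings County	NY	
county	New York County	NY	
county	Queens County	NY	
county	Richmond County	NY	
county	Mecklenburg County	NC	
county	Cuyahoga County	OH	
county	Franklin County	OH	
county	Hamilton County	OH	
county	Oklahoma County	OK	
county	Tulsa County	OK	
county	Multnomah County	OR	
county	Philadelphia County	PA	
county	Shelby County	TN	
county	Bexar County	TX	
county	Dallas County	TX	
county	Harris County	TX	
county	Tarrant County	TX	
county	Travis County	TX	
county	King County	WA	
county	District of Columbia	DC	
county	Jefferson County	AL	
county	Anchorage Municipality	AK	
county	Pulaski County	AR	
county	Denver County	CO	
county	Hartford County	CT	
county	New Castle County	DE	
county	Honolulu County	HI	
county	Ada County	ID	
county	Polk County	IA	
county	Sedgwick County	KS	
county	Jefferson County	KY	
county	Cumberland County	ME	
county	Hinds County	MS	
county	Jackson County	MO	
county	Yellowstone County	MT	
county	Douglas County	NE	
county	Hillsborough County	NH	
county	Bernalillo County	NM	
county	Cass County	ND	
county	Providence County	RI	
county	Richland County	SC	
county	Minnehaha County	SD	
county	Salt Lake County	UT	
county	Chittenden County	VT	
county	Fairfax County	VA	
county	Kanawha County	WV	
county	Milwaukee County	WI	
county	Laramie County	WY	
city	Phoenix	AZ	Maricopa County
city	Los Angeles	CA	Los Angeles County
city	San Francisco	CA	San Francisco County
city	San Diego	CA	San Diego County
city	Sacramento	CA	Sacramento County
city	Oakland	CA	Alameda County
city	Riverside	CA	Riverside County
city	San Bernardino	CA	San Bernardino County
city	Anaheim	CA	Orange County
city	San Mateo	CA	San Mateo County
city	Miami	FL	Miami-Dade County
city	Orlando	FL	Orange County
city	Tampa	FL	Hillsborough County
city	Jacksonville	FL	Duval County
city	Fort Lauderdale	FL	Broward County
city	St Petersburg	FL	Pinellas County
city	West Palm Beach	FL	Palm Beach County
city	Atlanta	GA	Fulton County
city	Decatur	GA	DeKalb County
city	Marietta	GA	Cobb County
city	Chicago	IL	Cook County
city	Springfield	IL	Sangamon County
city	Springfield	MA	Hampden County
city	Indianapolis	IN	Marion County
city	New Orleans	LA	Orleans Parish
city	Baton Rouge	LA	East Baton Rouge Parish
city	Baltimore	MD	Baltimore City
city	Silver Spring	MD	Montgomery County
city	Boston	MA	Suffolk County
city	Detroit	MI	Wayne County
city	Minneapolis	MN	Hennepin County
city	Las Vegas	NV	Clark County
city	Newark	NJ	Essex County
city	Jersey City	NJ	Hudson County
city	New York City	NY	New York County
city	Brooklyn	NY	Kings County
city	Bronx	NY	Bronx County
city	Queens	NY	Queens County
city	Staten Island	NY	Richmond County
city	Charlotte	NC	Mecklenburg County
city	Cleveland	OH	Cuyahoga County
city	Columbus	OH	Franklin County
city	Cincinnati	OH	Hamilton County
city	Oklahoma City	OK	Oklahoma County
city	Tulsa	OK	Tulsa County
city	Portland	OR	Multnomah County
city	Portland	ME	Cumberland County
city	Philadelphia	PA	Philadelphia County
city	Memphis	TN	Shelby County
city	San Antonio	TX	Bexar County
city	Dallas	TX	Dallas County
city	Houston	TX	Harris County
city	Fort Worth	TX	Tarrant County
city	Austin	TX	Travis County
city	Seattle	WA	King County
city	Birmingham	AL	Jefferson County
city	Anchorage	AK	Anchorage Municipality
city	Little Rock	AR	Pulaski County
city	Denver	CO	Denver County
city	Hartford	CT	Hartford County
city	Wilmington	DE	New Castle County
city	Honolulu	HI	Honolulu County
city	Boise	ID	Ada County
city	Des Moines	IA	Polk County
city	Wichita	KS	Sedgwick County
city	Louisville	KY	Jefferson County
city	Jackson	MS	Hinds County
city	Kansas City	MO	Jackson County
city	Billings	MT	Yellowstone County
city	Omaha	NE	Douglas County
city	Manchester	NH	Hillsborough County
city	Albuquerque	NM	Bernalillo County
city	Fargo	ND	Cass County
city	Providence	RI	Providence County
city	Columbia	SC	Richland County
city	Sioux Falls	SD	Minnehaha County
city	Salt Lake City	UT	Salt Lake County
city	Burlington	VT	Chittenden County
city	Fairfax	VA	Fairfax County
city	Charleston	WV	Kanawha County
city	Milwaukee	WI	Milwaukee County
city	Cheyenne	WY	Laramie County
alias	nyc	NY	New York County
alias	manhattan	NY	New York County
alias	philly	PA	Philadelphia County
alias	atl	GA	Fulton County
alias	sf	CA	San Francisco County
alias	nola	LA	Orleans Parish
alias	vegas	NV	Clark County
alias	washington dc	DC	District of Columbia
alias	socal	CA	
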