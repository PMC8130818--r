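region_id	name	macro_region
greater-london	Greater London	London
greater-manchester	Greater Manchester	North
merseyside	Merseyside	North
west-yorkshire	West Yorkshire	North
south-yorkshire	South Yorkshire	North
tyne-and-wear	Tyne and Wear	North
lancashire	Lancashire	North
cumbria	Cumbria	North
durham	County Durham	North
northumberland	Northumberland	North
cheshire	Cheshire	North
west-midlands	West Midlands	Midlands
staffordshire	Staffordshire	Midlands
derbyshire	Derbyshire	Midlands
nottinghamshire	Nottinghamshire	Midlands
leicestershire	Leicestershire	Midlands
warwickshire	Warwickshire	Midlands
lincolnshire	Lincolnshire	Midlands
norfolk	Norfolk	East
suffolk	Suffolk	East
essex	Essex	East
cambridgeshire	Cambridgeshire	East
hertfordshire	Hertfordshire	East
kent	Kent	South
surrey	Surrey	South
hampshire	Hampshire	South
east-sussex	East Sussex	South
west-sussex	West Sussex	South
oxfordshire	Oxfordshire	South
berkshire	Berkshire	South
devon	Devon	South West
cornwall	Cornwall	South West
somerset	Somerset	South West
bristol	Bristol	South West
gloucestershire	Gloucestershire	South West
cardiff	Cardiff	Wales
swansea	Swansea	Wales
glasgow	Glasgow	Scotland
edinburgh	Edinburgh	Scotland
antrim	Antrim	Northern Ireland
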